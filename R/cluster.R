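#' Cluster features by correlation distance with average linkage
#'
#' Agglomerative clustering of feature profiles under the dissimilarity
#' `d(i, j) = 1 - Pearson r(i, j)` with average linkage (UPGMA on the
#' dissimilarity). Correlation distance is invariant to scaling and shifting
#' of individual features, so clusters reflect profile shape, not magnitude.
#'
#' @param mat Feature x sample numeric matrix; >= 2 features, each with
#'   nonzero variance across samples (correlation is undefined otherwise).
#' @return A `cluster_tree`: list with `merge`, `height`, `order`, `labels`
#'   (as in [stats::hclust()]), the underlying `hclust` object, and `support`
#'   (`NULL` until [bootstrap_support()] fills it).
#' @export
cluster_features <- function(mat) {
  stopifnot(is.matrix(mat))
  if (nrow(mat) < 2) {
    stop_blisshit("need >= 2 features to cluster", class = "blisshit_parameter_error")
  }
  v <- apply(mat, 1, var)
  if (any(v == 0 | !is.finite(v))) {
    bad <- (rownames(mat) %||% seq_len(nrow(mat)))[which(v == 0 | !is.finite(v))[1]]
    stop_blisshit("feature '%s' has zero variance; correlation distance undefined",
                  bad, class = "blisshit_domain_error")
  }
  d <- 1 - cor(t(mat))
  hc <- hclust(as.dist(d), method = "average")
  structure(list(merge = hc$merge, height = hc$height, order = hc$order,
                 labels = hc$labels %||% as.character(seq_len(nrow(mat))),
                 hclust = hc, support = NULL, n_iterations = 0L),
            class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf("Feature cluster tree: %d leaves (correlation distance, average linkage)\n",
              length(x$labels)))
  if (!is.null(x$support)) {
    cat(sprintf("  bootstrap support over %d iterations; min %.2f, median %.2f\n",
                x$n_iterations, min(x$support), median(x$support)))
  }
  invisible(x)
}

#' @export
plot.cluster_tree <- function(x, ...) {
  plot(x$hclust, ...)
  invisible(x)
}

# sorted leaf-label sets of the internal nodes, one canonical string each
node_leaf_sets <- function(hc, labels) {
  n <- nrow(hc$merge)
  sets <- vector("list", n)
  for (k in seq_len(n)) {
    kids <- hc$merge[k, ]
    sets[[k]] <- c(if (kids[1] < 0) labels[-kids[1]] else sets[[kids[1]]],
                   if (kids[2] < 0) labels[-kids[2]] else sets[[kids[2]]])
  }
  vapply(sets, function(s) paste(sort(s), collapse = "\r"), "")
}

#' Bootstrap branch support for a feature cluster tree
#'
#' Resamples the samples (columns) with replacement `n_iterations` times,
#' reclusters each resample, and scores every internal branch of the original
#' tree by the fraction of iterations in which exactly its leaf set reappears
#' as a cluster. This is the plain bootstrap-proportion estimator of branch
#' stability (not a multiscale or perturbation-calibrated variant), and is
#' labelled as such in the output. Deterministic for a fixed seed.
#'
#' @param mat Feature x sample matrix (see [cluster_features()]).
#' @param n_iterations Number of bootstrap resamples (>= 1; 1000 for
#'   publication-grade support values).
#' @param seed Integer seed.
#' @return A `cluster_tree` with `support`: one value in \[0, 1\] per
#'   internal node (in `merge` order), plus `n_iterations` and
#'   `support_method`.
#' @export
bootstrap_support <- function(mat, n_iterations = 1000, seed = 1L) {
  if (!is.numeric(n_iterations) || n_iterations < 1) {
    stop_blisshit("`n_iterations` must be >= 1", class = "blisshit_parameter_error")
  }
  n_iterations <- as.integer(n_iterations)
  tree <- cluster_features(mat)
  base_sets <- node_leaf_sets(tree$hclust, tree$labels)
  counts <- integer(length(base_sets))
  with_seed(seed, {
    for (i in seq_len(n_iterations)) {
      idx <- sample.int(ncol(mat), replace = TRUE)
      sub <- mat[, idx, drop = FALSE]
      d <- 1 - suppressWarnings(cor(t(sub)))
      d[!is.finite(d)] <- 1  # zero-variance resample: treat as uncorrelated
      hc <- hclust(as.dist(d), method = "average")
      counts <- counts + (base_sets %in% node_leaf_sets(hc, tree$labels))
    }
  })
  tree$support <- counts / n_iterations
  tree$n_iterations <- n_iterations
  tree$support_method <- "bootstrap proportion (column resampling, exact leaf-set match)"
  tree
}

#' Export a cluster tree as Newick
#'
#' Branch supports (when present) are written as internal node labels, the
#' convention phylogenetics viewers expect.
#'
#' @param tree A `cluster_tree`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  stopifnot(inherits(tree, "cluster_tree"))
  phy <- ape::as.phylo(tree$hclust)
  if (!is.null(tree$support)) {
    base_sets <- node_leaf_sets(tree$hclust, tree$labels)
    parts <- ape::prop.part(phy)
    part_sets <- vapply(parts, function(idx) {
      paste(sort(attr(parts, "labels")[idx]), collapse = "\r")
    }, "")
    phy$node.label <- as.character(round(tree$support[match(part_sets, base_sets)], 3))
  }
  ape::write.tree(phy, file = path)
  invisible(path)
}
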