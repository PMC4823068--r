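#' Specify ground truth for a synthetic feature-by-sample log2 matrix
#'
#' Describes a profiling-style data set (protein-array epitopes or
#' transcripts) on the log2 scale: a feature count, a sample sheet, a sparse
#' map of planted treatment effects, and Gaussian feature noise. When
#' `pair_structure` is set, the control and treated sample of each
#' (line, replicate) pair share a per-pair random baseline, the situation a
#' paired test exploits.
#'
#' @param n_features Number of features (>= 1).
#' @param samples Data frame with columns `line`, `treatment`, `replicate`;
#'   one row per sample (column of the matrix).
#' @param effect_map Data frame with columns `feature` (index or id),
#'   `treatment`, `shift` (log2 units), or `NULL` for a global null. Features
#'   absent from the map have expected log2 fold change 0.
#' @param pair_structure Do control/treated replicates share a pair baseline?
#' @param noise_sd Per-entry Gaussian noise sd on the log2 scale (>= 0).
#' @param baseline Grand mean log2 abundance.
#' @param seed Integer seed.
#' @return A `matrix_truth` object.
#' @seealso [generate_matrix()], [demo_matrix_truth()]
#' @export
matrix_truth <- function(n_features, samples, effect_map = NULL,
                         pair_structure = TRUE, noise_sd = 0.25,
                         baseline = 10, seed = 1L) {
  if (!is.numeric(n_features) || n_features < 1) {
    stop_blisshit("`n_features` must be >= 1", class = "blisshit_parameter_error")
  }
  if (!is.data.frame(samples) || nrow(samples) == 0) {
    stop_blisshit("`samples` must be a non-empty data frame",
                  class = "blisshit_parameter_error")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop_blisshit("`noise_sd` must be >= 0", class = "blisshit_parameter_error")
  }
  stopifnot(all(c("line", "treatment", "replicate") %in% names(samples)))
  if (is.null(effect_map)) {
    effect_map <- data.frame(feature = integer(), treatment = character(),
                             shift = numeric())
  }
  structure(list(n_features = as.integer(n_features), samples = samples,
                 effect_map = effect_map, pair_structure = pair_structure,
                 noise_sd = noise_sd, baseline = baseline,
                 seed = as.integer(seed)),
            class = "matrix_truth")
}

#' Simulate a feature-by-sample log2 matrix with planted effects
#'
#' Each entry is `feature baseline + pair baseline + planted shift + noise`.
#' Feature baselines are drawn once per feature; pair baselines (per feature
#' and (line, replicate) pair, shared across treatments) are drawn only when
#' the truth has `pair_structure`; noise is iid `Normal(0, noise_sd)`.
#'
#' @param truth A [matrix_truth()] object.
#' @return A numeric matrix (features x samples) with feature ids as rownames,
#'   `line_treatment_replicate` colnames, and the truth attached as attribute
#'   `truth`.
#' @export
generate_matrix <- function(truth) {
  stopifnot(inherits(truth, "matrix_truth"))
  smp <- truth$samples
  p <- truth$n_features
  n <- nrow(smp)
  feat_ids <- sprintf("F%03d", seq_len(p))
  with_seed(truth$seed, {
    mat <- matrix(truth$baseline + rep(rnorm(p, 0, 1), n), p, n)
    if (isTRUE(truth$pair_structure)) {
      pair <- paste(smp$line, smp$replicate, sep = "\r")
      upair <- unique(pair)
      pb <- matrix(rnorm(p * length(upair), 0, 1), p, length(upair))
      mat <- mat + pb[, match(pair, upair), drop = FALSE]
    }
    em <- truth$effect_map
    if (nrow(em)) {
      fi <- if (is.numeric(em$feature)) as.integer(em$feature)
            else match(em$feature, feat_ids)
      for (k in seq_len(nrow(em))) {
        j <- which(smp$treatment == em$treatment[k])
        mat[fi[k], j] <- mat[fi[k], j] + em$shift[k]
      }
    }
    mat <- mat + matrix(rnorm(p * n, 0, truth$noise_sd), p, n)
  })
  dimnames(mat) <- list(feat_ids,
                        paste(smp$line, smp$treatment, smp$replicate, sep = "_"))
  structure(mat, truth = truth)
}

#' Demonstration profiling truth: phosphosite-scale paired design
#'
#' 114 features (the scale of a phosphosite antibody panel) on a 12-line
#' panel, each line contributing one control and one treated sample as a pair.
#' A planted minority of features (default 20) shifts by +/-1 log2 unit under
#' treatment, in two coherent blocks (all-up and all-down) so that clustering
#' on fold changes has recoverable structure.
#'
#' @param n_features,n_lines Matrix scale; defaults 114 features, 12 lines.
#' @param n_affected Number of features with a planted treatment effect.
#' @param shift Absolute log2 shift of affected features.
#' @param noise_sd Gaussian noise sd (log2 scale).
#' @param seed Integer seed.
#' @return A [matrix_truth()] object.
#' @export
demo_matrix_truth <- function(n_features = 114, n_lines = 12,
                              n_affected = 20, shift = 1, noise_sd = 0.25,
                              seed = 202L) {
  samples <- merge(data.frame(line = sprintf("MEL%02d", seq_len(n_lines))),
                   data.frame(treatment = c("control", "treated")), by = NULL)
  samples$replicate <- 1L
  n_up <- ceiling(n_affected / 2)
  effect_map <- data.frame(
    feature = seq_len(n_affected),
    treatment = "treated",
    shift = rep(c(shift, -shift), c(n_up, n_affected - n_up))
  )
  matrix_truth(n_features, samples, effect_map, pair_structure = TRUE,
               noise_sd = noise_sd, seed = seed)
}
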