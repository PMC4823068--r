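# End-to-end orchestration: generate/ingest -> normalize -> score ->
# threshold -> call -> summarize, with a manifest for reproducibility.

#' Read or build a run configuration
#'
#' Configurations are plain lists (or a YAML file of the same shape) with the
#' screen defaults baked in: 98th-percentile hit threshold, per-primary
#' pooling, 1 percent FDR for profiling.
#'
#' @param config A list, or path to a YAML file.
#' @return Validated config list.
#' @export
load_run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(percentile = 98, pooling = "per_primary",
                   pool = "statistics", fdr = 0.01, bootstrap = 1000,
                   seed = 1L)
  config <- modifyList(defaults, config)
  if (!is.numeric(config$percentile) || config$percentile <= 0 ||
      config$percentile >= 100) {
    stop_blisshit("config: percentile must lie in (0, 100), got %s",
                  format(config$percentile), class = "blisshit_config_error")
  }
  if (!is.numeric(config$fdr) || config$fdr <= 0 || config$fdr >= 1) {
    stop_blisshit("config: fdr must lie in (0, 1)", class = "blisshit_config_error")
  }
  if (!config$pooling %in% c("per_primary", "global")) {
    stop_blisshit("config: pooling must be 'per_primary' or 'global'",
                  class = "blisshit_config_error")
  }
  config
}

write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  df <- df[!vapply(df, is.list, TRUE)]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_manifest <- function(out_dir, files, config, seed, log_lines) {
  writeLines(log_lines, file.path(out_dir, "run.log"))
  files <- c(files, file.path(out_dir, "run.log"))
  manifest <- list(
    package = "blisshit",
    version = as.character(utils::packageVersion("blisshit")),
    seed = seed,
    config = config[order(names(config))],
    files = lapply(sort(files), function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  file.path(out_dir, "manifest.json")
}

#' Run the combination-screen pipeline
#'
#' Ingests a well table (or simulates one from a screen truth), validates the
#' design, normalizes to vehicle controls, scores every combination by Bliss
#' independence, calibrates the empirical percentile threshold, calls hits,
#' and writes the report bundle (scores, hit table, overlap partition,
#' average-synergy summary, manifest with content hashes) to `out_dir`.
#'
#' @param config List (or YAML path) with either `wells` (path to a well-table
#'   CSV) or `truth` (a [screen_truth()]; defaults to [demo_screen_truth()]
#'   when both are absent), plus optional `percentile`, `pooling`, `pool`,
#'   `seed`, described in [load_run_config()].
#' @param out_dir Output directory (created if needed); `NULL` to skip
#'   writing.
#' @return Invisibly, a list with `wells`, `design`, `profile`, `records`,
#'   `hits`, `partition`, `summary`, and `manifest` (path or `NULL`).
#' @export
run_screen_pipeline <- function(config = list(), out_dir = NULL) {
  config <- load_run_config(config)
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    message(line)
    log_lines <<- c(log_lines, line)
  }
  simulated <- FALSE
  if (!is.null(config$wells)) {
    wells <- read_well_table(config$wells)
    say("ingest: read %d wells from %s", nrow(wells), config$wells)
  } else {
    truth <- config$truth %||% demo_screen_truth(seed = config$seed)
    truth$seed <- config$seed %||% truth$seed
    wells <- generate_screen(truth)
    simulated <- TRUE
    say("simulate: generated %d wells (%d lines, seed %d)", nrow(wells),
        length(truth$lines), truth$seed)
  }
  design <- validate_design(wells)
  say("design: %d lines, %d primaries, %d secondaries, n = %d",
      length(design$lines), length(design$primaries), design$n_secondaries,
      design$replicates)
  profile <- normalize_to_vehicle(wells)
  say("normalize: %d conditions", nrow(profile$conditions))
  records <- score_screen(profile)
  say("score: %d combination-dose cells", nrow(records))
  hits <- screen_hits(records, percentile = config$percentile,
                      pooling = config$pooling, pool = config$pool)
  thr <- attr(hits, "threshold")
  say("threshold (%s, p%g): %s", config$pooling, config$percentile,
      paste(sprintf("%s=%.4f", names(thr) %||% "global", thr), collapse = ", "))
  say("hits: %d of %d combinations", sum(hits$hit), nrow(hits))
  partition <- if (length(design$primaries) >= 2) overlap_partition(hits) else NULL
  summary_tab <- average_synergy_summary(records)

  manifest <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- character()
    if (simulated) {
      files <- c(files, write_well_table(wells, file.path(out_dir, "wells.csv")))
      truth_echo <- attr(wells, "truth")
      truth_echo$hill_params$key <- NULL
      jsonlite::write_json(unclass(truth_echo),
                           file.path(out_dir, "truth.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      files <- c(files, file.path(out_dir, "truth.json"))
    }
    files <- c(files,
               write_tsv(profile$conditions, file.path(out_dir, "cytotoxicity.tsv")),
               write_tsv(records, file.path(out_dir, "synergy_scores.tsv")),
               write_tsv(hits, file.path(out_dir, "hit_table.tsv")))
    if (!is.null(partition)) {
      jsonlite::write_json(partition, file.path(out_dir, "overlap_partition.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      files <- c(files, file.path(out_dir, "overlap_partition.json"))
    }
    files <- c(files,
               write_tsv(summary_tab, file.path(out_dir, "average_synergy.tsv")))
    cfg_echo <- config
    cfg_echo$truth <- NULL
    manifest <- write_manifest(out_dir, files, cfg_echo, config$seed, log_lines)
  }
  invisible(list(wells = wells, design = design, profile = profile,
                 records = records, hits = hits, partition = partition,
                 summary = summary_tab, manifest = manifest))
}

#' Run the molecular-profiling pipeline
#'
#' Takes a feature x sample log2 matrix (path to TSV with feature ids in the
#' first column, an in-memory matrix, or a [matrix_truth()] to simulate),
#' pairs treated against control samples, computes paired moderated t-tests
#' with BH FDR control, clusters features on their fold-change profiles with
#' bootstrap branch support, and writes the fold-change table, the Newick
#' tree, and a manifest.
#'
#' @param config List (or YAML path) with `matrix` (path or matrix) or
#'   `truth` (a [matrix_truth()]; default [demo_matrix_truth()]), optional
#'   `pairing` data frame (`treated`, `control` column names; inferred from
#'   `_control_` / `_treated_` sample-name structure when absent), `fdr`,
#'   `bootstrap`, `prior_df`, `seed`.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return Invisibly, list with `matrix`, `diffs`, `table`, `tree`,
#'   `manifest`.
#' @export
run_profiling_pipeline <- function(config = list(), out_dir = NULL) {
  config <- load_run_config(config)
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    message(line)
    log_lines <<- c(log_lines, line)
  }
  mat <- config$matrix
  if (is.null(mat)) {
    truth <- config$truth %||% demo_matrix_truth(seed = config$seed)
    truth$seed <- config$seed %||% truth$seed
    mat <- generate_matrix(truth)
    say("simulate: %d features x %d samples (seed %d)", nrow(mat), ncol(mat),
        truth$seed)
  } else if (is.character(mat)) {
    mat <- read_matrix_tsv(mat)
    say("ingest: %d features x %d samples", nrow(mat), ncol(mat))
  }
  pairing <- config$pairing
  if (is.null(pairing)) {
    cn <- colnames(mat)
    ctrl <- grep("_control_", cn, value = TRUE)
    trt <- grep("_treated_", cn, value = TRUE)
    if (length(ctrl) == 0 || length(trt) != length(ctrl)) {
      stop_blisshit("cannot infer pairing from sample names; supply `pairing`",
                    class = "blisshit_config_error")
    }
    key <- function(x) sub("_(control|treated)_", "_", x)
    pairing <- data.frame(treated = trt[match(key(ctrl), key(trt))],
                          control = ctrl)
    if (anyNA(pairing$treated)) {
      stop_blisshit("pairing mismatch: control sample '%s' has no treated partner",
                    pairing$control[which(is.na(pairing$treated))[1]],
                    class = "blisshit_config_error")
    }
  }
  fc <- paired_log2_fc(mat, mat, pairing)
  say("pairing: %d pairs", ncol(fc$diffs))
  tab <- moderated_t(fc$diffs, prior_df = config$prior_df, fdr = config$fdr)
  say("moderated t: %d of %d features significant at %g%% FDR (prior df %.2f)",
      sum(tab$significant), nrow(tab), 100 * config$fdr, attr(tab, "df_prior"))
  tree <- bootstrap_support(fc$diffs, n_iterations = config$bootstrap,
                            seed = config$seed)
  say("clustering: %d leaves, %d bootstrap iterations", length(tree$labels),
      tree$n_iterations)

  manifest <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- c(
      write_tsv(tab, file.path(out_dir, "fold_change_table.tsv")),
      write_matrix_tsv(fc$diffs, file.path(out_dir, "paired_log2fc.tsv")),
      write_tree_newick(tree, file.path(out_dir, "cluster_tree.nwk")))
    cfg_echo <- config
    cfg_echo$truth <- NULL
    cfg_echo$matrix <- NULL
    cfg_echo$pairing <- NULL
    manifest <- write_manifest(out_dir, files, cfg_echo, config$seed, log_lines)
  }
  invisible(list(matrix = mat, diffs = fc$diffs, table = tab, tree = tree,
                 manifest = manifest))
}

#' Read / write a feature-by-sample matrix as TSV
#'
#' Feature ids in the first column, sample names in the header.
#'
#' @param path File path.
#' @return `read_matrix_tsv`: a numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[-1])
  rownames(m) <- df[[1]]
  m
}

#' @param mat Matrix to write.
#' @rdname read_matrix_tsv
#' @return `write_matrix_tsv`: `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(feature = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
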