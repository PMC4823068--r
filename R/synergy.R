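#' Bliss-predicted combination cytotoxicity
#'
#' Under Bliss independence two drugs act through independent mechanisms, so
#' the expected combined effect of fractional cytotoxicities `a` and `b` is
#' `1 - (1 - a)(1 - b)`. The form is symmetric in its arguments and works even
#' when one agent is inactive alone.
#'
#' @param c_primary,c_secondary Single-agent fractional cytotoxicities in
#'   \[0, 1\].
#' @return Predicted additive combination cytotoxicity in \[0, 1\].
#' @export
bliss_predicted <- function(c_primary, c_secondary) {
  assert_fraction(c_primary, "c_primary")
  assert_fraction(c_secondary, "c_secondary")
  1 - (1 - c_primary) * (1 - c_secondary)
}

#' Bliss synergy score of an observed combination
#'
#' The synergy score is the observed combination cytotoxicity minus the
#' Bliss-predicted value: positive scores indicate synergism, scores near
#' zero additivity, and negative scores antagonism.
#'
#' @param c_combination Observed combination cytotoxicity in \[0, 1\].
#' @param c_primary,c_secondary Single-agent cytotoxicities in \[0, 1\].
#' @return Score in \[-1, 1\].
#' @examples
#' synergy_score(0.90, 0.4, 0.3)  # 0.32: synergistic
#' synergy_score(0.58, 0.4, 0.3)  # 0: exactly additive
#' @export
synergy_score <- function(c_combination, c_primary, c_secondary) {
  assert_fraction(c_combination, "c_combination")
  c_combination - bliss_predicted(c_primary, c_secondary)
}

#' Score every combination cell of a screen
#'
#' For each (line, primary dose, secondary) grid cell, pulls the single-agent
#' cytotoxicities of the same line from the profile, forms the Bliss
#' prediction, and scores the observed combination. Replicate-level scores
#' (replicate k of the combination against replicate k of each single agent)
#' are retained alongside the replicate-mean score.
#'
#' @param profile A `cytotox_profile` from [normalize_to_vehicle()]; it must
#'   contain the single-agent condition for every drug + dose appearing in a
#'   combination.
#' @return A `synergy_records` data frame, one row per combination-dose cell,
#'   with columns `line`, `primary`, `primary_dose`, `secondary`,
#'   `secondary_dose`, `c_primary`, `c_secondary`, `c_combination`,
#'   `bliss_predicted`, `score`, and list column `rep_scores`.
#' @export
score_screen <- function(profile) {
  stopifnot(inherits(profile, "cytotox_profile"))
  cond <- profile$conditions
  ckey <- paste(cond$line, cond$primary, cond$primary_dose,
                cond$secondary, cond$secondary_dose, sep = "\r")
  combo <- cond[cond$primary != "vehicle" & cond$secondary != "none", ]
  if (nrow(combo) == 0) {
    stop_blisshit("profile contains no combination conditions",
                  class = "blisshit_validation_error")
  }
  pkey <- paste(combo$line, combo$primary, combo$primary_dose, "none", 0,
                sep = "\r")
  skey <- paste(combo$line, "vehicle", 0, combo$secondary,
                combo$secondary_dose, sep = "\r")
  ip <- match(pkey, ckey)
  is <- match(skey, ckey)
  bad <- which(is.na(ip) | is.na(is))
  if (length(bad)) {
    b <- bad[1]
    miss <- if (is.na(ip[b])) {
      sprintf("(%s, %s, %g)", combo$line[b], combo$primary[b],
              combo$primary_dose[b])
    } else {
      sprintf("(%s, %s, %g)", combo$line[b], combo$secondary[b],
              combo$secondary_dose[b])
    }
    stop_blisshit("missing single-agent condition %s", miss,
                  class = "blisshit_validation_error")
  }
  cp <- cond$mean[ip]
  cs <- cond$mean[is]
  bliss <- 1 - (1 - cp) * (1 - cs)
  score <- combo$mean - bliss
  rep_scores <- lapply(seq_len(nrow(combo)), function(k) {
    vc <- combo$values[[k]]; vp <- cond$values[[ip[k]]]
    vs <- cond$values[[is[k]]]
    n <- min(length(vc), length(vp), length(vs))
    vc[seq_len(n)] - (1 - (1 - vp[seq_len(n)]) * (1 - vs[seq_len(n)]))
  })
  out <- data.frame(combo[c("line", "primary", "primary_dose",
                            "secondary", "secondary_dose")],
                    c_primary = cp, c_secondary = cs,
                    c_combination = combo$mean,
                    bliss_predicted = bliss, score = score,
                    row.names = NULL)
  out$rep_scores <- I(rep_scores)
  structure(out, class = c("synergy_records", "data.frame"))
}

#' Empirical percentile threshold of a score distribution
#'
#' The hit cutoff of the screen is calibrated empirically: the given
#' percentile (default the 98th) of the pooled synergy-score distribution,
#' using the nearest-rank definition (the smallest score with at least
#' `percentile` percent of the distribution at or below it; no
#' interpolation). The realized upper-tail mass — the fraction of scores
#' strictly above the threshold — is attached as attribute `tail_mass`.
#'
#' @param scores At least 50 pooled synergy scores.
#' @param percentile Percentile in (0, 100); default 98.
#' @return The threshold, with attributes `percentile` and `tail_mass`.
#' @export
empirical_threshold <- function(scores, percentile = 98) {
  scores <- scores[is.finite(scores)]
  if (length(scores) < 50) {
    stop_blisshit(
      "need >= 50 scores for a stable percentile threshold; pool across lines/doses",
      class = "blisshit_parameter_error")
  }
  if (!is.numeric(percentile) || length(percentile) != 1 ||
      percentile <= 0 || percentile >= 100) {
    stop_blisshit("`percentile` must lie in (0, 100)",
                  class = "blisshit_parameter_error")
  }
  srt <- sort(scores)
  thr <- srt[ceiling(percentile / 100 * length(srt))]
  structure(thr, percentile = percentile,
            tail_mass = mean(scores > thr))
}

# statistic per (line, primary, secondary): max over the dose grid of the
# replicate-mean score
combination_statistics <- function(records) {
  agg <- stats::aggregate(list(statistic = records$score),
                          records[c("line", "primary", "secondary")], max)
  agg[order(agg$primary, agg$line, agg$secondary), , drop = FALSE]
}

#' Call hits against a synergy threshold
#'
#' Collapses dose-level scores to one statistic per (line, primary, secondary)
#' combination — the maximum over the dose grid of the replicate-mean score —
#' and flags a hit when the statistic strictly exceeds the threshold
#' ("greater than", not "at least": a statistic exactly at the cutoff is not
#' a hit).
#'
#' @param records A `synergy_records` data frame from [score_screen()].
#' @param threshold Scalar cutoff, or a named vector keyed by primary drug.
#' @param percentile Optional percentile annotation carried into the table.
#' @return A `hit_table` data frame (`line`, `primary`, `secondary`,
#'   `statistic`, `threshold`, `hit`) with attributes `threshold` and
#'   `percentile`.
#' @export
call_hits <- function(records, threshold, percentile = NA_real_) {
  if (is.null(records) || nrow(records) == 0) {
    out <- data.frame(line = character(), primary = character(),
                      secondary = character(), statistic = numeric(),
                      threshold = numeric(), hit = logical())
    return(structure(out, class = c("hit_table", "data.frame"),
                     threshold = threshold, percentile = percentile))
  }
  if (any(abs(threshold) > 1)) {
    stop_blisshit("threshold must lie in [-1, 1]",
                  class = "blisshit_domain_error")
  }
  stats_tab <- combination_statistics(records)
  thr <- if (!is.null(names(threshold))) {
    unname(threshold[stats_tab$primary])
  } else {
    rep_len(as.numeric(threshold), nrow(stats_tab))
  }
  if (anyNA(thr)) {
    stop_blisshit("no threshold supplied for primary '%s'",
                  stats_tab$primary[which(is.na(thr))[1]],
                  class = "blisshit_parameter_error")
  }
  stats_tab$threshold <- thr
  stats_tab$hit <- stats_tab$statistic > thr
  rownames(stats_tab) <- NULL
  structure(stats_tab, class = c("hit_table", "data.frame"),
            threshold = threshold, percentile = percentile)
}

#' Calibrate a percentile threshold and call hits in one step
#'
#' Pools scores, takes the empirical percentile threshold, and calls hits.
#' Pooling is per primary drug by default (each anchor drug gets its own
#' threshold from its own score distribution) or global. The percentile can
#' be taken over the combination statistics themselves (`pool =
#' "statistics"`, the default, which makes the realized hit fraction match
#' the nominal tail mass) or over the dose-level scores (`pool = "scores"`).
#'
#' @param records A `synergy_records` data frame.
#' @param percentile Percentile for [empirical_threshold()]; default 98.
#' @param pooling `"per_primary"` or `"global"`.
#' @param pool Distribution the percentile is taken over: `"statistics"`
#'   (one value per combination) or `"scores"` (one per combination-dose).
#' @return A `hit_table`; see [call_hits()].
#' @export
screen_hits <- function(records, percentile = 98,
                        pooling = c("per_primary", "global"),
                        pool = c("statistics", "scores")) {
  pooling <- match.arg(pooling)
  pool <- match.arg(pool)
  values <- if (pool == "statistics") {
    st <- combination_statistics(records)
    split(st$statistic, st$primary)
  } else {
    split(records$score, records$primary)
  }
  threshold <- if (pooling == "global") {
    as.numeric(empirical_threshold(unlist(values), percentile))
  } else {
    vapply(values, function(v) as.numeric(empirical_threshold(v, percentile)),
           0)
  }
  call_hits(records, threshold, percentile = percentile)
}

#' Partition secondary drugs by which primaries they synergize with
#'
#' For every non-empty subset of primary drugs, the secondary drugs that are
#' hits (in at least one cell line) with exactly that subset of primaries —
#' the cells of a Venn diagram over the anchor drugs.
#'
#' @param hits A `hit_table` covering at least two primary drugs, or a named
#'   list of per-primary hit tables.
#' @return List with `sets` (named list mapping subset labels like
#'   `"P1+P2"` to character vectors of secondaries) and `counts`.
#' @export
overlap_partition <- function(hits) {
  if (is.data.frame(hits)) {
    tab <- hits
  } else {
    stopifnot(is.list(hits), !is.null(names(hits)))
    tab <- do.call(rbind, lapply(names(hits), function(p) {
      h <- as.data.frame(hits[[p]]); h$primary <- p; h
    }))
  }
  primaries <- sort(unique(tab$primary))
  if (length(primaries) < 2) {
    stop_blisshit("overlap is defined for >= 2 primary drugs",
                  class = "blisshit_parameter_error")
  }
  hit_sets <- lapply(primaries, function(p) {
    sort(unique(tab$secondary[tab$primary == p & tab$hit]))
  })
  names(hit_sets) <- primaries
  all_sec <- sort(unique(unlist(hit_sets)))
  member <- vapply(hit_sets, function(s) all_sec %in% s,
                   logical(length(all_sec)))
  member <- matrix(member, nrow = length(all_sec),
                   dimnames = list(all_sec, primaries))
  subset_of <- apply(member, 1, function(m) {
    paste(primaries[m], collapse = "+")
  })
  subsets <- unlist(lapply(seq_along(primaries), function(k) {
    apply(combn(primaries, k), 2, paste, collapse = "+")
  }))
  sets <- lapply(subsets, function(s) all_sec[subset_of == s])
  names(sets) <- subsets
  list(sets = sets, counts = vapply(sets, length, 1L))
}

#' Average Bliss-predicted versus average observed cytotoxicity
#'
#' Per (line, secondary): the mean Bliss-predicted and the mean observed
#' combination cytotoxicity over the primary-dose grid. Points on the
#' diagonal are additive; vertical offset above the diagonal equals the mean
#' synergy score by linearity.
#'
#' @param records A `synergy_records` data frame.
#' @return Data frame with columns `line`, `secondary`, `primary` (when
#'   grouping by primary), `mean_predicted`, `mean_observed`, `mean_score`,
#'   `n_cells`.
#' @param by_primary Also split by primary drug (default `TRUE`).
#' @export
average_synergy_summary <- function(records, by_primary = TRUE) {
  if (is.null(records) || nrow(records) == 0) {
    stop_blisshit("no synergy records to summarize",
                  class = "blisshit_parameter_error")
  }
  keys <- if (by_primary) c("line", "secondary", "primary")
          else c("line", "secondary")
  agg <- stats::aggregate(
    records[c("bliss_predicted", "c_combination", "score")],
    records[keys], mean)
  cnt <- stats::aggregate(list(n_cells = records$score), records[keys], length)
  out <- merge(agg, cnt, by = keys, sort = TRUE)
  names(out)[names(out) == "bliss_predicted"] <- "mean_predicted"
  names(out)[names(out) == "c_combination"] <- "mean_observed"
  names(out)[names(out) == "score"] <- "mean_score"
  out
}
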