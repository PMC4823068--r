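#' Paired log2 fold changes between treated and control matrices
#'
#' @param treated,control Feature-by-sample matrices on the log2 scale,
#'   sharing rownames (features).
#' @param pairing Data frame with columns `treated`, `control` naming the
#'   paired columns (a bijection), or `NULL` to pair columns by position.
#' @return List with `diffs` (feature x pair matrix of treated - control
#'   log2 differences) and `log2_fc` (per-feature mean over pairs).
#' @export
paired_log2_fc <- function(treated, control, pairing = NULL) {
  stopifnot(is.matrix(treated), is.matrix(control))
  if (!identical(rownames(treated), rownames(control))) {
    stop_blisshit("treated and control matrices must share features",
                  class = "blisshit_validation_error")
  }
  if (is.null(pairing)) {
    if (ncol(treated) != ncol(control)) {
      stop_blisshit("positional pairing needs equal column counts",
                    class = "blisshit_validation_error")
    }
    ti <- seq_len(ncol(treated)); ci <- seq_len(ncol(control))
  } else {
    stopifnot(all(c("treated", "control") %in% names(pairing)))
    ti <- match(pairing$treated, colnames(treated))
    ci <- match(pairing$control, colnames(control))
    if (anyNA(ti) || anyNA(ci)) {
      bad <- c(pairing$treated[is.na(ti)], pairing$control[is.na(ci)])[1]
      stop_blisshit("sample '%s' in pairing not found in its matrix", bad,
                    class = "blisshit_validation_error")
    }
    if (anyDuplicated(ti) || anyDuplicated(ci)) {
      stop_blisshit("pairing must be a bijection (a sample appears twice)",
                    class = "blisshit_validation_error")
    }
  }
  diffs <- treated[, ti, drop = FALSE] - control[, ci, drop = FALSE]
  colnames(diffs) <- if (is.null(pairing)) colnames(treated)[ti]
                     else paste(pairing$treated, pairing$control, sep = "-")
  list(diffs = diffs, log2_fc = rowMeans(diffs))
}

# Empirical-Bayes prior (d0, s0^2) for per-feature variances s2 on df degrees
# of freedom, by moment matching on log variances: E[log s^2] and
# Var[log s^2] of a scaled chi-square involve digamma/trigamma, so the prior
# df solves trigamma(d0/2) = Var(log s2) - trigamma(df/2).
estimate_variance_prior <- function(s2, df) {
  ok <- s2 > 0 & is.finite(s2)
  if (sum(ok) < 2) return(list(df_prior = 0, s2_prior = mean(s2[ok])))
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  target <- mean((e - mean(e))^2 * sum(ok) / (sum(ok) - 1)) - trigamma(df / 2)
  if (!is.finite(target) || target <= 0) {
    return(list(df_prior = Inf, s2_prior = exp(mean(e))))
  }
  # invert trigamma by monotone bisection on d0/2
  lo <- 1e-8; hi <- 1e8
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (trigamma(mid) > target) lo <- mid else hi <- mid
  }
  d0 <- 2 * sqrt(lo * hi)
  s2_prior <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(df_prior = d0, s2_prior = s2_prior)
}

#' Moderated paired t-tests with BH false discovery rate control
#'
#' One-sample empirical-Bayes moderated t-tests on a matrix of paired
#' differences. Per-feature variances are shrunk toward a pooled prior under a
#' scaled-inverse-chi-square model whose prior degrees of freedom and scale
#' are estimated by moment matching on the log variances; the moderated
#' statistic is `t = mean / sqrt(s2_post / n)` on `n - 1 + d0` degrees of
#' freedom, with `s2_post = (d0 s0^2 + (n-1) s^2) / (d0 + n - 1)`. With
#' `prior_df = 0` this is the classical paired t-test; with `prior_df = Inf`
#' all features share the pooled variance. Two-sided p-values get
#' Benjamini-Hochberg adjustment.
#'
#' @param diffs Feature x pair matrix of paired (treated - control) log2
#'   differences; >= 2 pairs, and >= 10 features for a stable prior.
#' @param prior_df Prior degrees of freedom `d0`; `NULL` (default) estimates
#'   it from the data, `0` gives the classical test, `Inf` full pooling.
#' @param fdr Significance cutoff on the adjusted p-value (default 0.01, a
#'   1 percent false discovery rate).
#' @return A `fold_change_table` data frame: `feature`, `log2_fc`, `t`,
#'   `df_total`, `p_value`, `q_value`, `significant`; attributes `df_prior`,
#'   `s2_prior`, `fdr`.
#' @export
moderated_t <- function(diffs, prior_df = NULL, fdr = 0.01) {
  stopifnot(is.matrix(diffs))
  n <- ncol(diffs)
  if (n < 2) {
    stop_blisshit("need >= 2 pairs per feature", class = "blisshit_parameter_error")
  }
  if (is.null(prior_df) && nrow(diffs) < 10) {
    stop_blisshit("need >= 10 features to estimate the variance prior",
                  class = "blisshit_parameter_error")
  }
  m <- rowMeans(diffs)
  s2 <- apply(diffs, 1, var)
  df <- n - 1
  if (is.null(prior_df)) {
    prior <- estimate_variance_prior(s2, df)
  } else if (is.infinite(prior_df)) {
    prior <- list(df_prior = Inf, s2_prior = mean(s2))
  } else {
    prior <- list(df_prior = prior_df,
                  s2_prior = if (prior_df > 0) mean(s2) else NA_real_)
  }
  d0 <- prior$df_prior
  s2_post <- if (is.infinite(d0)) {
    rep(prior$s2_prior, length(s2))
  } else if (d0 == 0) {
    s2
  } else {
    (d0 * prior$s2_prior + df * s2) / (d0 + df)
  }
  t_stat <- m / sqrt(s2_post / n)
  df_total <- df + d0
  p <- 2 * pt(-abs(t_stat), df = df_total)
  q <- bh_adjust(p)
  out <- data.frame(feature = rownames(diffs) %||% seq_len(nrow(diffs)),
                    log2_fc = m, t = t_stat, df_total = df_total,
                    p_value = p, q_value = q, significant = q <= fdr,
                    row.names = NULL)
  structure(out, class = c("fold_change_table", "data.frame"),
            df_prior = d0, s2_prior = prior$s2_prior, fdr = fdr)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Order-preserving step-up adjustment with monotonicity enforcement, capped
#' at 1. Adjusted values never fall below the raw p-values.
#'
#' @param p Raw p-values in \[0, 1\].
#' @return Adjusted q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1)) {
    stop_blisshit("p-values must lie in [0, 1]", class = "blisshit_domain_error")
  }
  p.adjust(p, method = "BH")
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact permutation p-value by full enumeration of all `choose(nA+nB, nA)`
#' rank assignments when the combined sample size is at most `exact_max`
#' (ties handled with midranks); otherwise the normal approximation with tie
#' and continuity correction. The two-sided p is the permutation mass of rank
#' sums at least as far from their null mean as the observed one.
#'
#' @param a,b Numeric vectors, each with >= 2 values.
#' @param exact_max Largest combined sample size for full enumeration
#'   (default 12).
#' @return List with `p_value`, `statistic` (rank sum of `a`), and `method`
#'   ("exact enumeration" or "normal approximation").
#' @export
rank_sum <- function(a, b, exact_max = 12) {
  if (length(a) < 2 || length(b) < 2) {
    stop_blisshit("each group needs >= 2 values", class = "blisshit_parameter_error")
  }
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(na)])
  mu <- na * (n + 1) / 2
  if (n <= exact_max) {
    sets <- combn(n, na)
    w_all <- colSums(matrix(r[sets], nrow = na))
    p <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
    method <- "exact enumeration"
  } else {
    ties <- table(r)
    sigma2 <- na * (n - na) / 12 *
      ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (abs(w_obs - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-max(z, 0)))
    method <- "normal approximation"
  }
  list(p_value = p, statistic = w_obs, method = method)
}

#' Percent inhibition of a readout relative to control
#'
#' `100 * (1 - treated / control)`. Negative values (the readout rises under
#' treatment, e.g. paradoxical pathway activation) are reported as negative,
#' not clamped.
#'
#' @param treated,control Readout levels; `control` must be > 0.
#' @return Percent inhibition.
#' @export
percent_inhibition <- function(treated, control) {
  if (any(!is.finite(control)) || any(control <= 0)) {
    stop_blisshit("control level must be > 0", class = "blisshit_domain_error")
  }
  100 * (1 - treated / control)
}
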