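#' Normalize well fluorescence to per-line vehicle controls
#'
#' Cytotoxicity of a treated well is `1 - RFU / vehicle_mean` for that well's
#' cell line, clamped to \[0, 1\]. The Bliss model needs fractional effects in
#' \[0, 1\], so apparent growth stimulation (readout above the vehicle mean)
#' is clamped to 0; the unclamped value is kept alongside for diagnostics.
#' Replicate wells of a condition are aggregated to mean and standard error.
#'
#' @param wells A `well_table` data frame; every line present must have at
#'   least one vehicle well.
#' @return A `cytotox_profile` object: list with `wells` (per-well clamped and
#'   raw cytotoxicity), `conditions` (per-condition replicate values, `n`,
#'   `mean`, `sem`), and `vehicle_means` (per line).
#' @export
normalize_to_vehicle <- function(wells) {
  stopifnot(is.data.frame(wells), nrow(wells) > 0)
  veh <- wells$primary == "vehicle" & wells$secondary == "none"
  vm <- tapply(wells$rfu[veh], wells$line[veh], mean)
  missing <- setdiff(unique(wells$line), names(vm))
  if (length(missing)) {
    stop_blisshit(
      "line(s) %s lack vehicle wells: cytotoxicity cannot be normalized",
      paste(missing, collapse = ", "), class = "blisshit_validation_error")
  }
  w <- as.data.frame(wells)
  w$cytotox_raw <- 1 - w$rfu / unname(vm[w$line])
  w$cytotox <- clamp01(w$cytotox_raw)

  treated <- w[!(w$primary == "vehicle" & w$secondary == "none"), ]
  key <- c("line", "primary", "primary_dose", "secondary", "secondary_dose")
  grp <- interaction(treated[key], drop = TRUE, lex.order = TRUE)
  first <- !duplicated(grp)
  cond <- treated[first, key]
  vals <- split(treated$cytotox, grp)
  vals <- vals[match(interaction(cond, drop = TRUE, lex.order = TRUE),
                     names(vals))]
  cond$n <- lengths(vals)
  cond$mean <- vapply(vals, mean, 0)
  cond$sem <- vapply(vals, function(v) {
    if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
  }, 0)
  cond$values <- I(unname(vals))
  rownames(cond) <- NULL
  structure(list(wells = w, conditions = cond,
                 vehicle_means = vm),
            class = "cytotox_profile")
}

#' @export
print.cytotox_profile <- function(x, ...) {
  cat(sprintf("Cytotoxicity profile: %d conditions on %d line(s), %d wells\n",
              nrow(x$conditions), length(x$vehicle_means), nrow(x$wells)))
  invisible(x)
}

#' Fit a Hill dose-response curve
#'
#' Least-squares fit of `C(d) = Emax * d^h / (d^h + IC50^h)` to mean
#' cytotoxicities, with IC50 parameterized on the log scale and box
#' constraints (`Emax` in \[0, 1.05\], `h` in \[0.2, 5\]). Initialization:
#' `Emax` at the maximum observed response, `IC50` at the dose nearest
#' half-max, `h = 1`. If the largest observed response is below 0.2 the line
#' is flagged resistant and no IC50 is extrapolated.
#'
#' @param doses Numeric vector of at least 4 distinct positive doses.
#' @param responses Mean fractional cytotoxicity at each dose.
#' @param resistant_below Largest-response cutoff under which the fit is
#'   flagged "resistant - IC50 not identifiable" (default 0.2).
#' @return A `hill_fit` object with elements `emax`, `ic50`, `slope`,
#'   `converged`, `resistant`, `residuals`, `rss`, and the data; supports
#'   `print()`, `coef()`, `predict()`, `plot()`.
#' @examples
#' d <- 10^seq(0, 3.5, length.out = 8)
#' fit <- fit_hill(d, hill_cytotoxicity(d, 0.95, 125, 1.3))
#' coef(fit)
#' doses_for_inhibition(fit, c(0.15, 0.25, 0.35))
#' @export
fit_hill <- function(doses, responses, resistant_below = 0.2) {
  stopifnot(is.numeric(doses), is.numeric(responses),
            length(doses) == length(responses))
  ok <- is.finite(doses) & is.finite(responses) & doses > 0
  doses <- doses[ok]; responses <- responses[ok]
  if (length(unique(doses)) < 4) {
    stop_blisshit("need >= 4 distinct positive doses to fit a Hill curve",
                  class = "blisshit_parameter_error")
  }
  base <- list(doses = doses, responses = responses,
               resistant = FALSE, converged = FALSE,
               emax = NA_real_, ic50 = NA_real_, slope = NA_real_,
               residuals = rep(NA_real_, length(doses)), rss = NA_real_)
  if (max(responses) < resistant_below) {
    base$resistant <- TRUE
    base$flag <- "resistant - IC50 not identifiable"
    return(structure(base, class = "hill_fit"))
  }
  emax0 <- min(max(responses), 1.05)
  ic50_0 <- doses[which.min(abs(responses - emax0 / 2))]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      responses ~ emax * doses^h / (doses^h + (10^lic50)^h),
      start = list(emax = emax0, lic50 = log10(ic50_0), h = 1),
      lower = c(emax = 0, lic50 = log10(min(doses)) - 3, h = 0.2),
      upper = c(emax = 1.05, lic50 = log10(max(doses)) + 3, h = 5),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    base$flag <- "fit did not converge"
    return(structure(base, class = "hill_fit"))
  }
  cf <- coef(fit)
  base$emax <- unname(cf["emax"])
  base$ic50 <- unname(10^cf["lic50"])
  base$slope <- unname(cf["h"])
  base$converged <- TRUE
  base$residuals <- responses -
    hill_cytotoxicity(doses, base$emax, base$ic50, base$slope)
  base$rss <- sum(base$residuals^2)
  structure(base, class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  if (x$resistant) {
    cat("Hill fit:", x$flag, sprintf("(max response %.3f)\n", max(x$responses)))
  } else if (!x$converged) {
    cat("Hill fit:", x$flag, "\n")
  } else {
    cat(sprintf("Hill fit: Emax = %.3f, IC50 = %.4g, slope = %.3f (RSS %.2e)\n",
                x$emax, x$ic50, x$slope, x$rss))
  }
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...) {
  c(emax = object$emax, ic50 = object$ic50, slope = object$slope)
}

#' @export
predict.hill_fit <- function(object, doses = object$doses, ...) {
  if (!object$converged) {
    stop_blisshit("cannot predict from an unconverged or resistant fit",
                  class = "blisshit_parameter_error")
  }
  hill_cytotoxicity(doses, object$emax, object$ic50, object$slope)
}

#' @export
residuals.hill_fit <- function(object, ...) object$residuals

#' @export
plot.hill_fit <- function(x, ...) {
  plot(x$doses, x$responses, log = "x", xlab = "dose", ylab = "cytotoxicity",
       ylim = c(0, 1), pch = 19, ...)
  if (x$converged) {
    d <- 10^seq(log10(min(x$doses)), log10(max(x$doses)), length.out = 200)
    graphics::lines(d, predict(x, d))
    graphics::abline(v = x$ic50, lty = 3)
  }
  invisible(x)
}

#' Invert a Hill curve to doses at target inhibition levels
#'
#' Analytic inverse `d = IC50 * (t / (Emax - t))^(1/h)`: the dose producing
#' each requested fractional inhibition on the fitted curve. Used to pick
#' anchor doses (for example ~15, 25 and 35 percent growth inhibition) before
#' running a combination screen.
#'
#' @param curve A converged `hill_fit` (or anything with `emax`, `ic50`,
#'   `slope` fields).
#' @param targets Target inhibition fractions, each strictly below `Emax`.
#' @return Named numeric vector of doses, one per target.
#' @export
doses_for_inhibition <- function(curve, targets = c(0.15, 0.25, 0.35)) {
  emax <- curve$emax; ic50 <- curve$ic50; h <- curve$slope
  if (!is.finite(emax) || !is.finite(ic50) || !is.finite(h)) {
    stop_blisshit("curve has no usable parameters (resistant/unconverged fit?)",
                  class = "blisshit_parameter_error")
  }
  bad <- targets[targets >= emax | targets <= 0]
  if (length(bad)) {
    stop_blisshit("target inhibition %s unreachable (Emax = %.3f)",
                  paste(bad, collapse = ", "), emax,
                  class = "blisshit_domain_error")
  }
  setNames(ic50 * (targets / (emax - targets))^(1 / h),
           paste0("t", targets))
}
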