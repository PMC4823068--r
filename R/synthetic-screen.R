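#' Specify ground truth for a synthetic combination screen
#'
#' Bundles everything needed to simulate a plate-level combination
#' cytotoxicity screen: the cell-line panel, the anchor ("primary") drugs with
#' their three dose levels, the library ("secondary") drugs with a single dose
#' each, per-(line, drug) Hill dose-response parameters, planted interaction
#' offsets, and the noise model. Ground-truth cytotoxicity of a combination is
#' Bliss-additive plus the planted offset delta, clamped to \[0, 1\], so a
#' planted delta is exactly the true synergy score wherever no clamping
#' occurs.
#'
#' @param lines Character vector of cell-line ids.
#' @param primaries Named list; one numeric vector of three doses (nM) per
#'   primary drug.
#' @param secondaries Named numeric vector; one dose (uM) per secondary drug.
#' @param hill_params Data frame with columns `line`, `drug`, `emax` (in
#'   \[0, 1\]), `ic50` (> 0, same unit as that drug's doses), `slope` (> 0).
#'   Every (line, drug) pair used by the design must be present.
#' @param interactions Data frame with columns `line`, `primary`, `secondary`,
#'   `delta` (additive cytotoxicity offset in \[-1, 1\]), or `NULL` for none.
#'   Triples absent from the table have delta exactly 0.
#' @param noise_cv Coefficient of variation of the multiplicative fluorescence
#'   noise (>= 0).
#' @param replicates Number of replicate wells per condition (>= 1).
#' @param n_vehicle Vehicle-control wells per line per replicate plate set.
#' @param baseline_rfu Fluorescence of an untreated well.
#' @param rfu_floor Smallest emitted fluorescence value (> 0); simulated
#'   readouts are truncated here so they stay physical.
#' @param seed Integer seed; identical truth + seed gives bit-identical output.
#' @return A `screen_truth` object.
#' @seealso [demo_screen_truth()], [generate_screen()], [true_cytotoxicity()]
#' @export
screen_truth <- function(lines, primaries, secondaries, hill_params,
                         interactions = NULL, noise_cv = 0.1, replicates = 3,
                         n_vehicle = 6, baseline_rfu = 5e4, rfu_floor = 1,
                         seed = 1L) {
  if (!is.numeric(replicates) || replicates < 1) {
    stop_blisshit("`replicates` must be >= 1", class = "blisshit_parameter_error")
  }
  if (!is.numeric(noise_cv) || noise_cv < 0) {
    stop_blisshit("`noise_cv` must be >= 0", class = "blisshit_parameter_error")
  }
  if (rfu_floor <= 0) {
    stop_blisshit("`rfu_floor` must be > 0", class = "blisshit_parameter_error")
  }
  stopifnot(is.character(lines), length(lines) > 0,
            is.list(primaries), length(primaries) > 0,
            is.numeric(secondaries), length(secondaries) > 0,
            is.data.frame(hill_params))
  if (any(vapply(primaries, length, 1L) != 3L)) {
    stop_blisshit("each primary drug needs exactly three dose levels",
                  class = "blisshit_parameter_error")
  }
  hill_params$key <- paste(hill_params$line, hill_params$drug, sep = "\r")
  needed <- expand.grid(line = lines,
                        drug = c(names(primaries), names(secondaries)),
                        stringsAsFactors = FALSE)
  missing <- setdiff(paste(needed$line, needed$drug, sep = "\r"), hill_params$key)
  if (length(missing)) {
    stop_blisshit("hill_params missing for (line, drug): %s",
                  paste(gsub("\r", ", ", utils::head(missing, 5)), collapse = "; "),
                  class = "blisshit_parameter_error")
  }
  with(hill_params, stopifnot(all(emax >= 0 & emax <= 1), all(ic50 > 0),
                              all(slope > 0)))
  if (!is.null(interactions)) {
    stopifnot(is.data.frame(interactions),
              all(c("line", "primary", "secondary", "delta") %in% names(interactions)))
    stopifnot(all(abs(interactions$delta) <= 1))
  } else {
    interactions <- data.frame(line = character(), primary = character(),
                               secondary = character(), delta = numeric())
  }
  structure(list(lines = lines, primaries = primaries,
                 secondaries = secondaries, hill_params = hill_params,
                 interactions = interactions, noise_cv = noise_cv,
                 replicates = as.integer(replicates),
                 n_vehicle = as.integer(n_vehicle),
                 baseline_rfu = baseline_rfu, rfu_floor = rfu_floor,
                 seed = as.integer(seed)),
            class = "screen_truth")
}

#' @export
print.screen_truth <- function(x, ...) {
  cat("Synthetic screen truth\n")
  cat(sprintf("  %d lines x %d primaries (3 doses each) x %d secondaries, n = %d\n",
              length(x$lines), length(x$primaries), length(x$secondaries),
              x$replicates))
  cat(sprintf("  planted interactions: %d, noise CV: %g, seed: %d\n",
              nrow(x$interactions), x$noise_cv, x$seed))
  invisible(x)
}

#' Hill cytotoxicity at a dose
#'
#' `C(d) = Emax * d^h / (d^h + IC50^h)`, with `C(0) = 0`: the minimal monotone
#' sigmoid consistent with a saturating single-agent dose-response.
#'
#' @param dose Dose (>= 0), in the same unit as `ic50`.
#' @param emax Maximal effect, in \[0, 1\].
#' @param ic50 Dose of half-maximal effect (> 0).
#' @param slope Hill coefficient (> 0).
#' @return Fractional cytotoxicity in \[0, emax\].
#' @export
hill_cytotoxicity <- function(dose, emax, ic50, slope) {
  ifelse(dose <= 0, 0, emax * dose^slope / (dose^slope + ic50^slope))
}

hill_lookup <- function(truth, line, drug) {
  i <- match(paste(line, drug, sep = "\r"), truth$hill_params$key)
  if (anyNA(i)) {
    bad <- paste(line, drug)[is.na(i)][1]
    stop_blisshit("no Hill parameters for (line, drug) '%s'", bad,
                  class = "blisshit_lookup_error")
  }
  truth$hill_params[i, c("emax", "ic50", "slope")]
}

delta_lookup <- function(truth, line, primary, secondary) {
  key <- paste(line, primary, secondary, sep = "\r")
  tab <- truth$interactions
  i <- match(key, paste(tab$line, tab$primary, tab$secondary, sep = "\r"))
  ifelse(is.na(i), 0, tab$delta[i])
}

#' True combination cytotoxicity under the generative model
#'
#' Ground truth is Bliss-additive in the single-agent Hill cytotoxicities plus
#' the planted interaction offset:
#' `clamp(1 - (1 - Cp)(1 - Cs) + delta, 0, 1)`. A dose of zero means that
#' agent contributes nothing.
#'
#' @param truth A [screen_truth()] object.
#' @param line Cell-line id.
#' @param primary,primary_dose Primary drug id and dose (nM); dose 0 for none.
#' @param secondary,secondary_dose Secondary drug id and dose (uM); dose 0 for
#'   none.
#' @return Fractional cytotoxicity in \[0, 1\].
#' @export
true_cytotoxicity <- function(truth, line, primary, primary_dose,
                              secondary, secondary_dose) {
  stopifnot(inherits(truth, "screen_truth"))
  if (!all(line %in% truth$lines)) {
    stop_blisshit("unknown cell line '%s'", setdiff(line, truth$lines)[1],
                  class = "blisshit_lookup_error")
  }
  if (any(primary_dose < 0) || any(secondary_dose < 0)) {
    stop_blisshit("doses must be >= 0", class = "blisshit_parameter_error")
  }
  n <- max(length(line), length(primary), length(primary_dose),
           length(secondary), length(secondary_dose))
  line <- rep_len(line, n); primary <- rep_len(primary, n)
  secondary <- rep_len(secondary, n)
  primary_dose <- rep_len(primary_dose, n)
  secondary_dose <- rep_len(secondary_dose, n)
  cp <- cs <- numeric(n)
  ip <- which(primary_dose > 0)
  if (length(ip)) {
    hp <- hill_lookup(truth, line[ip], primary[ip])
    cp[ip] <- hill_cytotoxicity(primary_dose[ip], hp$emax, hp$ic50, hp$slope)
  }
  is <- which(secondary_dose > 0)
  if (length(is)) {
    hs <- hill_lookup(truth, line[is], secondary[is])
    cs[is] <- hill_cytotoxicity(secondary_dose[is], hs$emax, hs$ic50, hs$slope)
  }
  delta <- numeric(n)
  ib <- which(primary_dose > 0 & secondary_dose > 0)
  if (length(ib)) {
    delta[ib] <- delta_lookup(truth, line[ib], primary[ib], secondary[ib])
  }
  clamp01(1 - (1 - cp) * (1 - cs) + delta)
}

# Full condition grid for one truth: vehicle, primaries alone at 3 doses,
# secondaries alone, and the primary-dose x secondary grid, per line.
screen_conditions <- function(truth) {
  prim <- do.call(rbind, lapply(names(truth$primaries), function(p) {
    data.frame(primary = p, primary_dose = truth$primaries[[p]],
               dose_level = seq_along(truth$primaries[[p]]))
  }))
  sec <- data.frame(secondary = names(truth$secondaries),
                    secondary_dose = unname(truth$secondaries))
  per_line <- rbind(
    data.frame(primary = "vehicle", primary_dose = 0, dose_level = 0L,
               secondary = "none", secondary_dose = 0),
    cbind(prim, secondary = "none", secondary_dose = 0),
    cbind(primary = "vehicle", primary_dose = 0, dose_level = 0L, sec),
    merge(prim, sec, by = NULL)
  )
  out <- merge(data.frame(line = truth$lines), per_line, by = NULL)
  out <- out[order(out$line, out$primary, out$dose_level, out$secondary), ]
  rownames(out) <- NULL
  out
}

#' Ground-truth synergy scores of a screen truth
#'
#' For every (line, primary, dose level, secondary) cell, the true single-agent
#' cytotoxicities, the Bliss-predicted combination effect, the true (possibly
#' clamped) combination cytotoxicity, and the resulting true synergy score.
#' Where no clamping occurs the score equals the planted delta exactly; the
#' `clamped` column flags cells where it does not.
#'
#' @param truth A [screen_truth()] object.
#' @return Data frame with one row per combination-dose cell.
#' @export
true_synergy_scores <- function(truth) {
  stopifnot(inherits(truth, "screen_truth"))
  grid <- screen_conditions(truth)
  grid <- grid[grid$primary != "vehicle" & grid$secondary != "none", ]
  hp <- hill_lookup(truth, grid$line, grid$primary)
  hs <- hill_lookup(truth, grid$line, grid$secondary)
  cp <- hill_cytotoxicity(grid$primary_dose, hp$emax, hp$ic50, hp$slope)
  cs <- hill_cytotoxicity(grid$secondary_dose, hs$emax, hs$ic50, hs$slope)
  bliss <- 1 - (1 - cp) * (1 - cs)
  delta <- delta_lookup(truth, grid$line, grid$primary, grid$secondary)
  combo <- clamp01(bliss + delta)
  data.frame(grid[c("line", "primary", "primary_dose", "dose_level",
                    "secondary", "secondary_dose")],
             c_primary = cp, c_secondary = cs, bliss_predicted = bliss,
             delta = delta, c_combination = combo, score = combo - bliss,
             clamped = combo != bliss + delta, row.names = NULL)
}

#' Simulate a plate-level combination screen
#'
#' Emits one well per (line, condition, replicate) — vehicle controls, each
#' primary alone at its three doses, each secondary alone, and the full
#' primary-dose x secondary grid — laid out row-wise on 96-well plates.
#' Fluorescence is `baseline * (1 - true cytotoxicity) * (1 + e)` with
#' `e ~ Normal(0, noise_cv)`, truncated at `rfu_floor` so readouts stay
#' positive.
#'
#' @param truth A [screen_truth()] object.
#' @return Object of class `well_table`: a data frame of well measurements
#'   (`plate_id`, `well`, `line`, drug/dose/unit columns, `replicate`, `rfu`)
#'   with the generating truth attached as attribute `truth`.
#' @export
generate_screen <- function(truth) {
  stopifnot(inherits(truth, "screen_truth"))
  cond <- screen_conditions(truth)
  # vehicle condition expands to n_vehicle wells; everything else to 1
  reps <- ifelse(cond$primary == "vehicle" & cond$secondary == "none",
                 truth$n_vehicle, 1L)
  cond <- cond[rep(seq_len(nrow(cond)), reps), ]
  wells <- merge(cond, data.frame(replicate = seq_len(truth$replicates)),
                 by = NULL)
  wells <- wells[order(wells$line, wells$replicate), ]
  rownames(wells) <- NULL

  ctox <- numeric(nrow(wells))
  single_p <- wells$secondary == "none" & wells$primary != "vehicle"
  single_s <- wells$primary == "vehicle" & wells$secondary != "none"
  combo <- wells$primary != "vehicle" & wells$secondary != "none"
  for (idx in list(which(single_p), which(single_s), which(combo))) {
    if (length(idx)) {
      ctox[idx] <- true_cytotoxicity(truth, wells$line[idx],
                                     wells$primary[idx], wells$primary_dose[idx],
                                     wells$secondary[idx], wells$secondary_dose[idx])
    }
  }

  rfu <- with_seed(truth$seed, {
    eps <- rnorm(nrow(wells), 0, truth$noise_cv)
    pmax(truth$baseline_rfu * (1 - ctox) * (1 + eps), truth$rfu_floor)
  })

  # plate layout: per (line, replicate), fill plates row-wise A1..H12
  coords <- paste0(rep(LETTERS[1:8], each = 12), rep(1:12, 8))
  key <- paste(wells$line, wells$replicate, sep = "\r")
  pos <- stats::ave(seq_along(key), key, FUN = seq_along) - 1L
  out <- data.frame(
    plate_id = sprintf("%s_R%d_P%02d", wells$line, wells$replicate,
                       pos %/% 96L + 1L),
    well = coords[pos %% 96L + 1L],
    line = wells$line,
    primary = wells$primary, primary_dose = wells$primary_dose,
    primary_dose_unit = ifelse(wells$primary == "vehicle", "", "nM"),
    secondary = wells$secondary, secondary_dose = wells$secondary_dose,
    secondary_dose_unit = ifelse(wells$secondary == "none", "", "uM"),
    replicate = wells$replicate,
    rfu = rfu,
    stringsAsFactors = FALSE
  )
  structure(out, class = c("well_table", "data.frame"), truth = truth)
}

#' Demonstration screen truth mirroring the study design
#'
#' A 12-line BRAF-mutant melanoma-style panel screened with three MAPK-pathway
#' anchor drugs (a selective RAF inhibitor, a pan-RAF inhibitor, and a MEK
#' inhibitor), each at three doses chosen analytically to give roughly 15, 25
#' and 35 percent inhibition on a panel-reference dose-response curve, against
#' 58 library compounds at one dose apiece. Per-line Hill parameters are drawn
#' around drug-specific reference curves with IC50 spread covering sensitive
#' through near-resistant lines. Synergistic interactions of size
#' `planted_delta` are planted on `planted_fraction` of (line, primary,
#' secondary) triples, chosen deterministically among triples whose
#' Bliss-predicted cytotoxicity stays at least `planted_delta` + 0.02 below 1
#' at every dose, so the planted offset is always fully expressed (never
#' clamped) and remains a legible ground truth.
#'
#' @param n_lines,n_secondaries Panel size; defaults 12 and 58.
#' @param noise_cv Fluorescence noise CV; 0 for a noise-free oracle screen.
#' @param replicates Wells per condition (default 3, triplicate).
#' @param planted_delta Size of planted synergy offsets (0 to plant none).
#' @param planted_fraction Fraction of combination triples that get an offset.
#' @param seed Integer seed controlling both panel parameters and noise.
#' @return A [screen_truth()] object.
#' @export
demo_screen_truth <- function(n_lines = 12, n_secondaries = 58,
                              noise_cv = 0.1, replicates = 3,
                              planted_delta = 0.35, planted_fraction = 0.02,
                              seed = 101L) {
  lines <- sprintf("MEL%02d", seq_len(n_lines))
  prim_ref <- data.frame(
    drug = c("PLX4720", "RAF265", "PD325901"),
    emax = 0.95, ic50 = c(200, 400, 20), slope = 1.2   # nM
  )
  with_seed(seed, {
    sec_ref <- data.frame(
      drug = sprintf("SEC%02d", seq_len(n_secondaries)),
      emax = 0.9,
      ic50 = 10^runif(n_secondaries, -0.5, 0.8),       # uM
      slope = runif(n_secondaries, 0.8, 1.6)
    )
    ref <- rbind(prim_ref, sec_ref)
    hp <- merge(data.frame(line = lines), ref, by = NULL)
    # sensitive -> near-resistant spread around the reference IC50
    hp$ic50 <- hp$ic50 * 10^runif(nrow(hp), -0.8, 1.5)
    hp$emax <- pmin(pmax(hp$emax * runif(nrow(hp), 0.85, 1.05), 0.3), 0.98)
    hp$slope <- hp$slope * runif(nrow(hp), 0.8, 1.25)
  })

  # anchor doses: analytic Hill inverse at 15/25/35% on the reference curve
  targets <- c(0.15, 0.25, 0.35)
  primaries <- setNames(lapply(seq_len(nrow(prim_ref)), function(i) {
    with(prim_ref[i, ], ic50 * (targets / (emax - targets))^(1 / slope))
  }), prim_ref$drug)
  # library compounds anchored near 20% inhibition on their reference curves
  secondaries <- setNames(
    sec_ref$ic50 * (0.2 / (sec_ref$emax - 0.2))^(1 / sec_ref$slope),
    sec_ref$drug)

  truth <- screen_truth(lines, primaries, secondaries,
                        hill_params = hp[c("line", "drug", "emax", "ic50", "slope")],
                        noise_cv = noise_cv, replicates = replicates,
                        seed = seed)
  if (planted_delta > 0 && planted_fraction > 0) {
    ts <- true_synergy_scores(truth)
    peak <- stats::aggregate(bliss_predicted ~ line + primary + secondary,
                             ts, max)
    eligible <- peak[peak$bliss_predicted <= 1 - planted_delta - 0.02, ]
    n_plant <- max(1L, floor(planted_fraction *
                               n_lines * length(primaries) * n_secondaries))
    n_plant <- min(n_plant, nrow(eligible))
    pick <- eligible[round(seq(1, nrow(eligible), length.out = n_plant)), ]
    truth$interactions <- data.frame(line = pick$line, primary = pick$primary,
                                     secondary = pick$secondary,
                                     delta = planted_delta)
  }
  truth
}
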