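make_wells <- function(rfu, line = "L1", primary = "vehicle", pdose = 0,
                       secondary = "none", sdose = 0, replicate = 1) {
  data.frame(plate_id = "P1", well = paste0("A", seq_along(rfu)), line = line,
             primary = primary, primary_dose = pdose, primary_dose_unit = "",
             secondary = secondary, secondary_dose = sdose,
             secondary_dose_unit = "", replicate = replicate, rfu = rfu)
}

test_that("vehicle normalization maps fluorescence to clamped cytotoxicity", {
  w <- rbind(make_wells(c(10000, 10000)),
             make_wells(4000, primary = "PX", pdose = 10)[1, ])
  w$well <- c("A1", "A2", "B1")
  p <- normalize_to_vehicle(w)
  expect_equal(p$conditions$mean, 0.6)

  # readout above the vehicle mean clamps to 0 but keeps the raw value
  w2 <- rbind(make_wells(10000), make_wells(12000, primary = "PX", pdose = 10))
  w2$well <- c("A1", "B1")
  p2 <- normalize_to_vehicle(w2)
  expect_equal(p2$conditions$mean, 0)
  expect_equal(p2$wells$cytotox_raw[2], -0.2)
})

test_that("replicates aggregate to mean and standard error", {
  w <- rbind(make_wells(10000),
             make_wells(c(5000, 4000, 3000), primary = "PX", pdose = 10,
                        replicate = 1:3))
  w$well <- paste0("A", 1:4)
  p <- normalize_to_vehicle(w)
  expect_equal(p$conditions$n, 3L)
  expect_equal(p$conditions$mean, 0.6)
  expect_equal(p$conditions$sem, sd(c(0.5, 0.6, 0.7)) / sqrt(3),
               tolerance = 1e-10)
  expect_equal(p$conditions$sem, 0.0577, tolerance = 1e-3)
})

test_that("normalizing a noise-free screen recovers the generator truth exactly", {
  tr <- tiny_truth(noise_cv = 0)
  p <- normalize_to_vehicle(generate_screen(tr))
  cond <- p$conditions
  single <- cond[cond$secondary == "none", ]
  truth_c <- true_cytotoxicity(tr, single$line, single$primary,
                               single$primary_dose, "none", 0)
  expect_equal(single$mean, truth_c, tolerance = 1e-12)
  expect_true(all(cond$mean >= 0 & cond$mean <= 1))
  w <- generate_screen(tr)
  expect_error(normalize_to_vehicle(w[w$primary != "vehicle", ]),
               "cannot be normalized")
})

test_that("Hill fits recover noiseless parameters and expose the model identity", {
  d <- 10^seq(0, 3.5, length.out = 8)
  fit <- fit_hill(d, hill_cytotoxicity(d, 1, 125, 1))
  expect_true(fit$converged)
  expect_lt(abs(fit$ic50 - 125) / 125, 0.01)
  expect_equal(predict(fit, fit$ic50), fit$emax / 2, tolerance = 1e-8)
  expect_equal(unname(coef(fit)), c(fit$emax, fit$ic50, fit$slope))
})

test_that("flat responders are flagged resistant instead of extrapolated", {
  d <- 10^seq(0, 3, length.out = 6)
  fit <- fit_hill(d, rep(0.05, 6))
  expect_true(fit$resistant)
  expect_match(fit$flag, "resistant")
  expect_true(is.na(fit$ic50))
  expect_error(predict(fit, 10), class = "blisshit_parameter_error")
  expect_error(fit_hill(c(1, 10, 100), c(0.1, 0.4, 0.7)),
               class = "blisshit_parameter_error")
})

test_that("parameter recovery stays accurate under assay-level noise", {
  set.seed(31)
  errs <- replicate(10, {
    emax <- runif(1, 0.7, 1); ic50 <- 10^runif(1, 1, 3); h <- runif(1, 0.7, 2.5)
    d <- ic50 * 10^seq(-2, 2, length.out = 8)
    resp <- vapply(d, function(x) {
      mean(pmin(pmax(hill_cytotoxicity(x, emax, ic50, h) + rnorm(3, 0, 0.02),
                     0), 1))
    }, 0)
    fit <- fit_hill(d, resp)
    abs(fit$ic50 - ic50) / ic50
  })
  expect_lt(median(errs), 0.1)
})

test_that("dose targeting is the analytic inverse of the fitted curve", {
  curve <- list(emax = 1, ic50 = 1, slope = 1)
  expect_equal(unname(doses_for_inhibition(curve, 0.25)), 1 / 3)
  expect_equal(unname(doses_for_inhibition(curve, 0.5)), 1)

  d <- 10^seq(0, 3.5, length.out = 8)
  fit <- fit_hill(d, hill_cytotoxicity(d, 0.9, 80, 1.6))
  targets <- c(0.15, 0.25, 0.35)
  doses <- doses_for_inhibition(fit, targets)
  expect_true(all(diff(doses) > 0))
  expect_equal(unname(predict(fit, doses)), targets, tolerance = 1e-9)
  expect_error(doses_for_inhibition(fit, 0.95), "unreachable")
})
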