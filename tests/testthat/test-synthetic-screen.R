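test_that("true combination cytotoxicity follows the Bliss-plus-offset model", {
  # Hill curve at dose = IC50 gives exactly Emax/2, so these are closed forms
  tr <- exact_truth()
  expect_equal(true_cytotoxicity(tr, "L1", "PX", 10, "SX", 2), 0.58)

  tr2 <- exact_truth(data.frame(line = "L1", primary = "PX", secondary = "SX",
                                delta = 0.35))
  expect_equal(true_cytotoxicity(tr2, "L1", "PX", 10, "SX", 2), 0.93)

  # large single-agent effects plus a big offset clamp at 1
  hp <- data.frame(line = "L1", drug = c("PX", "SX"),
                   emax = 0.9, ic50 = 1, slope = 1)
  tr3 <- screen_truth("L1", list(PX = c(1, 2, 1e6)), c(SX = 1e6), hp,
                      interactions = data.frame(line = "L1", primary = "PX",
                                                secondary = "SX", delta = 0.5))
  expect_equal(true_cytotoxicity(tr3, "L1", "PX", 1e6, "SX", 1e6), 1)

  # dose 0 means the agent contributes nothing
  expect_equal(true_cytotoxicity(tr, "L1", "PX", 0, "SX", 2), 0.3)
  expect_equal(true_cytotoxicity(tr, "L1", "PX", 10, "SX", 0), 0.4)
})

test_that("unknown ids and bad parameters are rejected by name", {
  tr <- tiny_truth()
  expect_error(true_cytotoxicity(tr, "NOPE", "PA", 10, "S1", 1), "NOPE")
  expect_error(true_cytotoxicity(tr, "L1", "PZ", 10, "S1", 1), "PZ")
  expect_error(tiny_truth(replicates = 0), class = "blisshit_parameter_error")
  expect_error(tiny_truth(noise_cv = -0.1), class = "blisshit_parameter_error")
  hp <- data.frame(line = "L1", drug = "PX", emax = 0.8, ic50 = 10, slope = 1)
  expect_error(
    screen_truth("L1", list(PX = c(1, 2, 3)), c(SX = 1), hp),
    "SX")
})

test_that("generated screens are deterministic and physically bounded", {
  tr <- tiny_truth(noise_cv = 0.3, seed = 7)
  w1 <- generate_screen(tr)
  w2 <- generate_screen(tr)
  expect_identical(as.data.frame(w1), as.data.frame(w2))
  expect_true(all(w1$rfu > 0))
  # a different seed changes the noise
  tr$seed <- 8L
  expect_false(identical(w1$rfu, generate_screen(tr)$rfu))
})

test_that("screen layout covers the full condition grid at the demo scale", {
  tr <- demo_screen_truth(noise_cv = 0, seed = 3)
  w <- generate_screen(tr)
  n_lines <- 12; n_prim <- 3; n_dose <- 3; n_sec <- 58
  cond <- unique(w[c("line", "primary", "primary_dose", "secondary",
                     "secondary_dose")])
  # per line: vehicle + primaries alone at 3 doses + secondaries alone + grid
  expect_equal(nrow(cond),
               n_lines * (1 + n_prim * n_dose + n_sec +
                            n_prim * n_dose * n_sec))
  # wells: vehicle condition holds n_vehicle wells, everything else one
  expect_equal(nrow(w),
               n_lines * tr$replicates *
                 (tr$n_vehicle + n_prim * n_dose + n_sec +
                    n_prim * n_dose * n_sec))
  expect_true(all(grepl("^[A-H](1[0-2]|[1-9])$", w$well)))
  expect_false(anyDuplicated(w[c("plate_id", "well")]) > 0)
  # true cytotoxicities never leave [0, 1]
  ts <- true_synergy_scores(tr)
  expect_true(all(ts$c_combination >= 0 & ts$c_combination <= 1))
})

test_that("noise-free generation inverts to zero synergy when nothing is planted", {
  w <- generate_screen(tiny_truth(noise_cv = 0))
  rec <- score_screen(normalize_to_vehicle(w))
  expect_equal(max(abs(rec$score)), 0, tolerance = 1e-12)
})

test_that("demo truth plants offsets only where they cannot be clamped", {
  tr <- demo_screen_truth(noise_cv = 0, seed = 19)
  ts <- true_synergy_scores(tr)
  planted <- ts[ts$delta > 0, ]
  expect_gt(nrow(planted), 0)
  expect_false(any(planted$clamped))
  expect_equal(planted$score, planted$delta)
})
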