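test_that("Bliss prediction and synergy score match the defining arithmetic", {
  expect_equal(bliss_predicted(0.4, 0.3), 0.58)
  expect_equal(bliss_predicted(0, 0.7), 0.7)   # inactive partner: identity
  expect_equal(bliss_predicted(1, 0.3), 1)     # complete kill: absorbing
  expect_equal(synergy_score(0.58, 0.4, 0.3), 0)
  expect_equal(synergy_score(0.90, 0.4, 0.3), 0.32)
  expect_equal(synergy_score(0.30, 0.5, 0.5), -0.45)
  expect_error(bliss_predicted(1.2, 0.3), class = "blisshit_domain_error")
  expect_error(synergy_score(-0.1, 0.3, 0.3), class = "blisshit_domain_error")
})

test_that("Bliss prediction is symmetric and scores bounded on a dense grid", {
  g <- seq(0, 1, length.out = 101)
  a <- rep(g, each = 101); b <- rep(g, times = 101)
  expect_equal(bliss_predicted(a, b), bliss_predicted(b, a))
  for (cc in c(0, 0.5, 1)) {
    s <- synergy_score(cc, a, b)
    expect_true(all(s >= -1 & s <= 1))
    # a fully cytotoxic single agent leaves no room for extra killing
    expect_true(all(s[a == 1 | b == 1] <= 0))
  }
})

test_that("screen scoring inverts the noise-free generator", {
  planted <- data.frame(line = "L2", primary = "PA", secondary = "S3",
                        delta = 0.35)
  tr <- tiny_truth(noise_cv = 0, interactions = planted)
  rec <- score_screen(normalize_to_vehicle(generate_screen(tr)))
  expect_identical(nrow(rec), 3L * 2L * 3L * 4L)  # lines x primaries x doses x secondaries
  is_planted <- rec$line == "L2" & rec$primary == "PA" & rec$secondary == "S3"
  expect_equal(rec$score[is_planted], rep(0.35, 3), tolerance = 1e-10)
  expect_equal(max(abs(rec$score[!is_planted])), 0, tolerance = 1e-12)
  # replicate-level scores agree with the replicate-mean in the noiseless case
  expect_equal(unname(vapply(rec$rep_scores, mean, 0)), rec$score,
               tolerance = 1e-10)
})

test_that("a missing single-agent condition is reported by name", {
  p <- normalize_to_vehicle(generate_screen(tiny_truth()))
  cond <- p$conditions
  drop <- !(cond$line == "L1" & cond$primary == "PA" &
              cond$primary_dose == 30 & cond$secondary == "none")
  p$conditions <- cond[drop, ]
  expect_error(score_screen(p), "L1, PA, 30")
})

test_that("the empirical threshold uses the nearest-rank percentile", {
  scores <- (1:100) / 100
  thr <- empirical_threshold(scores, 98)
  expect_equal(as.numeric(thr), 0.98)
  expect_equal(attr(thr, "tail_mass"), 0.02)
  # default percentile is the 98th
  expect_equal(as.numeric(empirical_threshold(scores)), 0.98)
  expect_equal(as.numeric(empirical_threshold(rep(0.4, 60), 50)), 0.4)
  expect_equal(as.numeric(empirical_threshold(rep(0.4, 60), 99)), 0.4)
  expect_error(empirical_threshold((1:10) / 10, 98), "pool")
  expect_error(empirical_threshold(scores, 200), class = "blisshit_parameter_error")
})

test_that("hit calling is strict at the threshold", {
  rec <- data.frame(line = "L1", primary = "P", secondary = c("a", "b", "c"),
                    primary_dose = 1, secondary_dose = 1,
                    score = c(0.27, 0.26, 0.20))
  h <- call_hits(rec, 0.26)
  expect_identical(h$hit, c(TRUE, FALSE, FALSE))
  expect_identical(nrow(call_hits(rec[0, ], 0.26)), 0L)
  expect_error(call_hits(rec, 1.5), class = "blisshit_domain_error")
})

test_that("the combination statistic is the max over the dose grid", {
  rec <- data.frame(line = "L1", primary = "P", secondary = "a",
                    primary_dose = c(1, 2, 3), secondary_dose = 1,
                    score = c(0.1, 0.4, 0.2))
  h <- call_hits(rec, 0.3)
  expect_identical(nrow(h), 1L)
  expect_equal(h$statistic, 0.4)
  expect_true(h$hit)
})

test_that("overlap partition performs the Venn set arithmetic", {
  mk <- function(p, secs, hit = TRUE) {
    data.frame(line = "L1", primary = p, secondary = secs,
               statistic = 0.5, threshold = 0.26, hit = hit)
  }
  tab <- rbind(mk("P1", c("a", "b", "c")), mk("P2", c("b", "c", "d")),
               mk("P3", "c"))
  part <- overlap_partition(tab)
  expect_identical(part$sets[["P1"]], "a")
  expect_identical(part$sets[["P1+P2"]], "b")
  expect_identical(part$sets[["P1+P2+P3"]], "c")
  expect_identical(part$sets[["P2"]], "d")
  expect_identical(sum(part$counts), 4L)

  disjoint <- rbind(mk("P1", "a"), mk("P2", "b"))
  expect_identical(overlap_partition(disjoint)$counts[["P1+P2"]], 0L)
  same <- rbind(mk("P1", c("a", "b")), mk("P2", c("a", "b")))
  p_same <- overlap_partition(same)
  expect_identical(p_same$counts[["P1+P2"]], 2L)
  expect_identical(sum(p_same$counts), 2L)
  expect_error(overlap_partition(mk("P1", "a")), class = "blisshit_parameter_error")
})

test_that("average synergy summaries are linear in the per-cell scores", {
  tr <- tiny_truth(noise_cv = 0.05, seed = 13)
  rec <- score_screen(normalize_to_vehicle(generate_screen(tr)))
  sm <- average_synergy_summary(rec)
  expect_equal(sm$mean_observed - sm$mean_predicted, sm$mean_score,
               tolerance = 1e-12)

  # uniform planted offset with no clamping shows up as a vertical offset
  delta_all <- expand.grid(line = tr$lines, primary = names(tr$primaries),
                           secondary = names(tr$secondaries),
                           stringsAsFactors = FALSE)
  delta_all$delta <- 0.2
  tr0 <- tiny_truth(noise_cv = 0, interactions = delta_all)
  rec0 <- score_screen(normalize_to_vehicle(generate_screen(tr0)))
  sm0 <- average_synergy_summary(rec0)
  expect_equal(sm0$mean_observed - sm0$mean_predicted, rep(0.2, nrow(sm0)),
               tolerance = 1e-10)
})

test_that("planted synergies are recovered at pre-registered operating bounds", {
  # bounds frozen from a one-time pilot at these exact conditions
  tr <- demo_screen_truth(noise_cv = 0.05, planted_delta = 0.35,
                          planted_fraction = 0.05, seed = 77)
  rec <- score_screen(normalize_to_vehicle(generate_screen(tr)))
  h <- call_hits(rec, 0.175)
  planted <- combo_key(tr$interactions)
  is_planted <- combo_key(h) %in% planted
  expect_gte(mean(h$hit[is_planted]), 0.99)
  expect_gte(mean(!h$hit[!is_planted]), 0.995)
})

test_that("detection rate rises monotonically with the planted offset", {
  base <- demo_screen_truth(n_lines = 6, n_secondaries = 20, noise_cv = 0.05,
                            planted_delta = 0.4, planted_fraction = 0.05,
                            seed = 55)
  rates <- vapply(c(0, 0.1, 0.2, 0.3, 0.4), function(delta) {
    tr <- base
    tr$interactions$delta <- delta
    rec <- score_screen(normalize_to_vehicle(generate_screen(tr)))
    h <- call_hits(rec, 0.15)
    mean(h$hit[combo_key(h) %in% combo_key(tr$interactions)])
  }, 0)
  expect_true(all(diff(rates) >= 0))
  expect_equal(rates[1], 0)
  expect_equal(rates[5], 1)
})
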