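test_that("paired log2 fold changes match a brute-force mean of differences", {
  set.seed(17)
  treated <- matrix(rnorm(15), 5, 3,
                    dimnames = list(paste0("f", 1:5), paste0("t", 1:3)))
  control <- matrix(rnorm(15), 5, 3,
                    dimnames = list(paste0("f", 1:5), paste0("c", 1:3)))
  pairing <- data.frame(treated = paste0("t", 1:3), control = paste0("c", 1:3))
  fc <- paired_log2_fc(treated, control, pairing)
  manual <- sapply(1:5, function(i) {
    mean(sapply(1:3, function(j) treated[i, j] - control[i, j]))
  })
  expect_equal(unname(fc$log2_fc), manual, tolerance = 1e-12)

  expect_equal(unname(paired_log2_fc(treated, treated)$log2_fc), rep(0, 5))
  expect_equal(unname(paired_log2_fc(treated + 1, treated)$log2_fc), rep(1, 5))

  bad <- pairing; bad$treated[2] <- "t9"
  expect_error(paired_log2_fc(treated, control, bad), "t9")
  dupl <- pairing; dupl$treated[2] <- "t1"
  expect_error(paired_log2_fc(treated, control, dupl), "bijection")
})

test_that("moderated t with zero prior df is the classical paired t-test", {
  set.seed(23)
  diffs <- matrix(rnorm(100 * 4, sd = runif(100, 0.5, 2)), 100, 4)
  tab <- moderated_t(diffs, prior_df = 0)
  for (i in c(1, 10, 50, 100)) {
    ct <- t.test(diffs[i, ])
    expect_equal(tab$t[i], unname(ct$statistic), tolerance = 1e-10)
    expect_equal(tab$p_value[i], ct$p.value, tolerance = 1e-10)
  }
})

test_that("infinite prior df pools all features onto one variance", {
  set.seed(29)
  diffs <- matrix(rnorm(50 * 3), 50, 3)
  tab <- moderated_t(diffs, prior_df = Inf)
  pooled <- mean(apply(diffs, 1, var))
  expect_equal(tab$t, rowMeans(diffs) / sqrt(pooled / 3), tolerance = 1e-12)
})

test_that("estimated moderation agrees with the reference empirical-Bayes fit", {
  set.seed(37)
  diffs <- matrix(rnorm(300 * 4, sd = rep(sqrt(1 / rgamma(300, 4, 4)), 4)),
                  300, 4)
  tab <- moderated_t(diffs)
  fit <- limma::lmFit(diffs, design = matrix(1, 4, 1))
  eb <- limma::eBayes(fit)
  expect_equal(attr(tab, "df_prior"), eb$df.prior, tolerance = 0.05)
  expect_equal(attr(tab, "s2_prior"), eb$s2.prior, tolerance = 0.02)
  expect_equal(tab$t, unname(eb$t[, 1]), tolerance = 1e-6)
  expect_equal(tab$p_value, unname(eb$p.value[, 1]), tolerance = 1e-6)
})

test_that("planted effects are all flagged at 1% FDR with controlled FDP", {
  set.seed(41)
  n_feat <- 200; n_pairs <- 6; n_planted <- 20; sdn <- 0.3
  fdp <- replicate(100, {
    diffs <- matrix(rnorm(n_feat * n_pairs, 0, sdn), n_feat, n_pairs)
    diffs[seq_len(n_planted), ] <- diffs[seq_len(n_planted), ] + 3 * sdn
    tab <- moderated_t(diffs)
    hits <- which(tab$significant)
    expect_true(all(seq_len(n_planted) %in% hits))
    fp <- sum(hits > n_planted)
    fp / max(1, length(hits))
  })
  expect_lte(mean(fdp), 0.02)
})

test_that("BH adjustment is the step-up procedure", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(bh_adjust(p), rep(0.04, 4))
  expect_equal(bh_adjust(p), stepup_bh(p), tolerance = 1e-12)
  set.seed(43)
  pr <- runif(200)^2
  expect_equal(bh_adjust(pr), stepup_bh(pr), tolerance = 1e-12)
  expect_true(all(bh_adjust(pr) >= pr))
  expect_true(all(bh_adjust(pr) <= 1))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 1.2)), class = "blisshit_domain_error")
})

test_that("rank-sum p-values are exact for small samples and match wilcox", {
  r <- rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p_value, 0.1)
  expect_identical(r$method, "exact enumeration")
  expect_equal(r$p_value, enumerate_rank_sum_p(c(1, 2, 3), c(4, 5, 6)))

  expect_equal(rank_sum(c(1, 1), c(1, 1))$p_value, 1)

  set.seed(47)
  for (i in 1:10) {
    a <- rnorm(4); b <- rnorm(5, 0.8)
    expect_equal(rank_sum(a, b)$p_value, enumerate_rank_sum_p(a, b),
                 tolerance = 1e-12)
    expect_equal(rank_sum(a, b)$p_value,
                 wilcox.test(a, b, exact = TRUE)$p.value, tolerance = 1e-12)
  }
  expect_error(rank_sum(1, c(2, 3)), class = "blisshit_parameter_error")
})

test_that("the normal approximation tracks the exact test at moderate n", {
  set.seed(53)
  for (i in 1:10) {
    a <- rnorm(12); b <- rnorm(12, 0.5)
    approx <- rank_sum(a, b)
    expect_identical(approx$method, "normal approximation")
    exact <- wilcox.test(a, b, exact = TRUE)$p.value
    expect_lt(abs(approx$p_value - exact), 0.02)
  }
})

test_that("percent inhibition keeps its sign convention", {
  expect_equal(percent_inhibition(0.2, 1.0), 80)
  expect_equal(percent_inhibition(1, 1), 0)
  expect_equal(percent_inhibition(1.5, 1.0), -50)  # paradoxical activation
  expect_error(percent_inhibition(0.5, 0), class = "blisshit_domain_error")
})
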