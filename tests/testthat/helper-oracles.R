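# Independent oracles and small fixtures shared across tests.

# Brute-force average-linkage agglomeration, O(n^3): at each step merge the
# pair of clusters with the smallest mean cross-pair dissimilarity. Returns
# merge heights in merge order. Deliberately naive and independent of hclust.
naive_average_linkage_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  active <- seq_along(clusters)
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(NA, NA); bh <- Inf
    for (i in 2:length(active)) {
      for (j in 1:(i - 1)) {
        h <- mean(d[clusters[[active[i]]], clusters[[active[j]]]])
        if (h < bh) { bh <- h; best <- c(i, j) }
      }
    }
    heights <- c(heights, bh)
    clusters[[length(clusters) + 1]] <-
      c(clusters[[active[best[1]]]], clusters[[active[best[2]]]])
    active <- c(active[-best], length(clusters))
  }
  heights
}

# Exact two-sided rank-sum p by full enumeration, written independently of
# rank_sum(): enumerate every subset of positions that could hold group A.
enumerate_rank_sum_p <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  mu <- na * (length(pooled) + 1) / 2
  w_obs <- sum(r[seq_len(na)])
  sets <- utils::combn(length(pooled), na)
  w_all <- apply(sets, 2, function(s) sum(r[s]))
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}

# Hand step-up BH: q_i = min over j >= i (ordered) of m * p_(j) / j, capped.
stepup_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(m * p[o] / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Small 3-line, 2-primary, 4-secondary screen truth with flat deterministic
# Hill parameters; fast enough for per-operation tests.
tiny_truth <- function(noise_cv = 0, seed = 1L, interactions = NULL,
                       replicates = 3) {
  lines <- c("L1", "L2", "L3")
  primaries <- list(PA = c(10, 30, 60), PB = c(5, 15, 40))
  secondaries <- c(S1 = 1, S2 = 2, S3 = 0.5, S4 = 1.5)
  hp <- expand.grid(line = lines, drug = c(names(primaries), names(secondaries)),
                    stringsAsFactors = FALSE)
  hp$emax <- ifelse(hp$drug %in% names(primaries), 0.8, 0.6)
  hp$ic50 <- ifelse(hp$drug %in% names(primaries), 50, 2)
  hp$slope <- 1
  screen_truth(lines, primaries, secondaries, hp,
               interactions = interactions, noise_cv = noise_cv,
               replicates = replicates, seed = seed)
}

# Truth engineered for exact closed-form cytotoxicities: at dose = IC50 the
# Hill curve sits at exactly Emax/2, so PX @ 10 gives 0.4 and SX @ 2 gives 0.3.
exact_truth <- function(interactions = NULL) {
  hp <- data.frame(line = "L1", drug = c("PX", "SX"),
                   emax = c(0.8, 0.6), ic50 = c(10, 2), slope = 1)
  screen_truth("L1", list(PX = c(5, 10, 20)), c(SX = 2), hp,
               interactions = interactions, noise_cv = 0)
}

combo_key <- function(d) paste(d$line, d$primary, d$secondary, sep = "|")

# Recompute the leaf set behind each internal node of a cluster tree from its
# merge matrix, independently of the implementation's own bookkeeping.
node_leaf_sets_test <- function(tree) {
  merge <- tree$merge; labels <- tree$labels
  sets <- vector("list", nrow(merge))
  out <- character(nrow(merge))
  for (k in seq_len(nrow(merge))) {
    grab <- function(x) if (x < 0) labels[-x] else sets[[x]]
    sets[[k]] <- c(grab(merge[k, 1]), grab(merge[k, 2]))
    out[k] <- paste(sort(sets[[k]]), collapse = "\r")
  }
  out
}
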