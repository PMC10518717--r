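test_that("the S0 statistic reduces to the pooled t statistic and handles degenerate rows", {
  set.seed(10)
  a <- rnorm(5, 1); b <- rnorm(5)
  st <- s0_t_statistic(a, b, s0 = 0)
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(st$d, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(s0_t_statistic(a, a)$d, 0)
  # zero-variance groups: s = 0, d = fc / s0
  expect_equal(s0_t_statistic(c(2, 2, 2), c(1, 1, 1), s0 = 0.5)$d, 2)
  # insufficient values: untestable, not an exception
  expect_true(is.na(s0_t_statistic(c(1, NA), c(1, 2, 3))$d))
  # antisymmetry under group swap
  expect_equal(s0_t_statistic(a, b, 0.3)$d, -s0_t_statistic(b, a, 0.3)$d)
})

test_that("s0 estimation follows the variance-stabilizing percentile search", {
  labels <- rep(c("A", "B"), each = 4)
  # constant s: all candidates equivalent, smallest returned, d order unchanged
  set.seed(11)
  shift <- rnorm(200)
  X <- matrix(1, 200, 8) + outer(shift, c(0, 0, 0, 0, 1, 1, 1, 1)) +
    matrix(rep(c(-1, 1), length.out = 8 * 200), 200, 8, byrow = TRUE) * 0.5
  s_vals <- apply(X, 1, function(r) s0_t_statistic(r[1:4], r[5:8])$s)
  expect_lt(diff(range(s_vals)), 1e-9)
  expect_equal(estimate_s0(X, labels), min(s_vals))
  # heteroscedastic null: chosen s0 > 0 and small-s rows no longer dominate |d|
  set.seed(12)
  sds <- rep(c(0.01, 1), each = 1000)
  Y <- matrix(rnorm(2000 * 8, 0, rep(sds, 8)), 2000, 8)
  s0 <- estimate_s0(Y, labels)
  expect_gt(s0, 0)
  d0 <- abs(apply(Y, 1, function(r) s0_t_statistic(r[1:4], r[5:8], 0)$d))
  dm <- abs(apply(Y, 1, function(r) s0_t_statistic(r[1:4], r[5:8], s0)$d))
  top0 <- mean(order(-d0)[1:100] <= 1000)   # fraction of top-|d| from small-s half
  topm <- mean(order(-dm)[1:100] <= 1000)
  expect_lt(topm, top0)
  expect_lt(topm, 0.9)
  # determinism
  expect_identical(estimate_s0(Y, labels), s0)
})

test_that("BH adjustment matches the hand-computed step-up values and is monotone", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  p <- sort(runif(50))
  expect_true(!is.unsorted(bh_fdr(p)))
  expect_error(bh_fdr(c(0.1, NA)), "finite")
  expect_error(bh_fdr(c(0.1, 1.2)), "0, 1")
})

test_that("sampled permutation FDR equals exhaustive enumeration on 3-vs-3 instances", {
  set.seed(42)
  X <- matrix(rnorm(30 * 6), 30, 6)
  X[1:3, 4:6] <- X[1:3, 4:6] + 3  # a few real effects
  rownames(X) <- paste0("r", 1:30)
  labels <- rep(c("A", "B"), each = 3)
  res <- suppressMessages(
    permutation_fdr(X, labels, test_config(n_permutations = 100, s0 = 0.1, seed = 7)))
  expect_true(attr(res, "exhaustive"))
  # independent brute-force oracle over all choose(6,3) = 20 shuffles
  dstat <- function(i1, i2) {
    m1 <- rowMeans(X[, i1]); m2 <- rowMeans(X[, i2])
    v1 <- apply(X[, i1], 1, var); v2 <- apply(X[, i2], 1, var)
    s <- sqrt(((2 * v1 + 2 * v2) / 4) * (2 / 3))
    (m1 - m2) / (s + 0.1)
  }
  obs <- abs(dstat(1:3, 4:6))
  sets <- combn(6, 3)
  perm <- sapply(seq_len(ncol(sets)), function(k)
    abs(dstat(sets[, k], setdiff(1:6, sets[, k]))))
  fdr_at <- function(t) min(1, mean(colSums(perm >= t)) / sum(obs >= t))
  thr <- sort(unique(obs))
  q_oracle <- sapply(obs, function(o) min(sapply(thr[thr <= o], fdr_at)))
  expect_equal(res$q, unname(q_oracle), tolerance = 1e-12)
  expect_equal(abs(res$d), unname(obs), tolerance = 1e-12)
})

test_that("identical groups yield zero significant rows", {
  set.seed(33)
  X <- matrix(rnorm(20 * 6), 20, 6)
  X[, 4:6] <- X[, 1:3]  # groups identical, nonzero within-group variance
  res <- suppressMessages(
    permutation_fdr(X, rep(c("A", "B"), each = 3), test_config(n_permutations = 50)))
  expect_equal(sum(res$significant), 0L)
})

test_that("simulated two-state profiles are recovered at FDR 0.05 in both modes", {
  sim <- gen_tmt_profile(profile_sim_config(
    n_proteins = 1000, channels_per_group = 5, frac_regulated = 0.1,
    effect_log2 = 2, effect_sd = 0, noise_sd_log2 = 0.2, missing_rate = 0,
    seed = 21))
  L <- log2(intensities(sim$matrix))
  labels <- channel_meta(sim$matrix)$condition
  perm <- differential_expression(L, labels,
    test_config(correction = "permutation", n_permutations = 250, s0 = 0.1, seed = 5))
  bh <- differential_expression(L, labels,
    test_config(correction = "benjamini-hochberg", s0 = 0.1))
  truth <- sim$truth$regulated
  for (res in list(perm, bh)) {
    recovered <- sum(res$significant & truth)
    expect_gte(recovered, 95)
    false_pos <- sum(res$significant & !truth)
    expect_lte(false_pos, 0.05 * sum(res$significant) + 3)
  }
  jac <- sum(perm$significant & bh$significant) / sum(perm$significant | bh$significant)
  expect_gt(jac, 0.9)
  # q-values invariant under row permutation
  set.seed(1); idx <- sample(nrow(L))
  perm2 <- differential_expression(L[idx, ], labels,
    test_config(correction = "permutation", n_permutations = 250, s0 = 0.1, seed = 5))
  expect_equal(perm2$q[match(perm$id, perm2$id)], perm$q)
})

test_that("fold-change bands use the closed boundary at |log2FC| = 1", {
  X <- cbind(matrix(0, 4, 3), matrix(rep(c(-1, 0.5, 1, 2.5), 3), 4, 3))
  res <- differential_expression(X, rep(c("B", "A"), each = 3),
                                 test_config(correction = "benjamini-hochberg"))
  expect_equal(res$band, c("1-2", "none", "1-2", ">2"))
  bc <- attr(res, "band_counts")
  expect_equal(unname(bc[["1-2"]]), 2L)
  expect_equal(unname(bc[[">2"]]), 1L)
})
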