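test_that("total-sum normalization equalizes channel totals to the mean of sums", {
  m <- matrix(c(10, 20, 30, 40, 30, 60, 90, 120), ncol = 2)  # sums 100 and 300
  tn <- total_sum_normalize(m)
  expect_equal(colSums(tn$matrix), c(200, 200), ignore_attr = TRUE)
  expect_equal(unname(tn$report$factors), c(2, 2/3))
  # already equal sums: identity up to float
  id <- total_sum_normalize(tn$matrix)
  expect_equal(id$matrix, tn$matrix, tolerance = 1e-12)
  # scaling one channel then renormalizing reproduces the original
  # normalization up to a single global factor (the target constant moves,
  # but all downstream ratios are unchanged)
  m2 <- m; m2[, 2] <- m2[, 2] * 10
  tn2 <- total_sum_normalize(m2)$matrix
  ratio <- tn2 / tn$matrix
  expect_lt(diff(range(ratio)), 1e-12 * mean(ratio))
  # missing values ignored in sums; all-missing channel is an error naming it
  m3 <- m; m3[1, 1] <- NA
  expect_silent(total_sum_normalize(m3))
  m4 <- m; m4[, 2] <- NA
  colnames(m4) <- c("ok", "bad")
  expect_error(total_sum_normalize(m4), "bad")
})

test_that("median centering matches the hand-computed toy factors and is idempotent", {
  # 4-row toy: per-channel medians 10 and 40, pooled median 20
  m <- matrix(c(5, 10, 10, 20, 20, 40, 40, 80), ncol = 2)
  expect_equal(apply(m, 2, median), c(10, 40))
  expect_equal(median(m), 20)
  mc <- median_center(m)
  expect_equal(unname(mc$report$factors), c(2, 0.5))
  expect_equal(apply(mc$matrix, 2, median), c(20, 20), ignore_attr = TRUE)
  # identical channels: identity
  mi <- cbind(a = c(1, 5, 9), b = c(1, 5, 9))
  expect_equal(median_center(mi)$matrix, mi, tolerance = 1e-12)
  # idempotent on random data
  set.seed(1)
  r <- matrix(2^rnorm(200, 20, 2), 40, 5)
  once <- median_center(r)$matrix
  twice <- median_center(once)$matrix
  expect_equal(twice, once, tolerance = 1e-12)
  # additive-on-log option also equalizes (geometric) medians
  lg <- median_center(r, on_log = TRUE)$matrix
  meds <- apply(log2(lg), 2, median)
  expect_lt(diff(range(meds)), 1e-9)
})

test_that("per-channel scalings preserve within-channel rank order", {
  set.seed(2)
  m <- matrix(2^rnorm(300, 20, 2), 60, 5)
  for (norm in list(total_sum_normalize, median_center)) {
    out <- norm(m)$matrix
    for (k in 1:5) expect_equal(order(out[, k]), order(m[, k]))
  }
})

test_that("bridge normalization cancels per-plex batch factors exactly", {
  set.seed(3)
  base <- matrix(2^rnorm(40, 20, 1), 10, 4)
  ch <- data.frame(label = c("s1", "s2", "s3", "bridge"),
                   condition = c("A", "A", "B", "bridge"),
                   bridge = c(FALSE, FALSE, FALSE, TRUE))
  plexA <- reporter_matrix(base, channels = transform(ch, plex = 1L))
  # identical plexes -> all ratios equal across plexes
  plexA2 <- reporter_matrix(base, channels = transform(ch, plex = 2L))
  j <- bridge_normalize(list(plexA, plexA2), "bridge")
  expect_equal(dim(j), c(10L, 6L))
  expect_equal(unname(intensities(j)[, 1:3]), unname(intensities(j)[, 4:6]))
  # global x2 batch factor on plex B cancels in the ratios
  plexB <- reporter_matrix(base * 2, channels = transform(ch, plex = 2L))
  j2 <- bridge_normalize(list(plexA, plexB), "bridge")
  expect_equal(unname(intensities(j2)[, 1:3]), unname(intensities(j2)[, 4:6]))
  # identical plexes of constant rows give ratio 1 everywhere
  ones <- reporter_matrix(matrix(5, 4, 4), channels = ch)
  expect_true(all(intensities(bridge_normalize(list(ones), "bridge")) == 1))
})

test_that("bridge normalization drops rows without a usable bridge value and logs them", {
  base <- matrix(2^seq(1, 8), 4, 2)
  ch <- data.frame(label = c("s1", "bridge"), bridge = c(FALSE, TRUE))
  pa <- reporter_matrix(base, channels = transform(ch, plex = 1L))
  mb <- base; mb[2, 2] <- NA  # protein 2 missing from plex B's bridge
  pb <- reporter_matrix(mb, rows = pa$rows, channels = transform(ch, plex = 2L))
  expect_message(j <- bridge_normalize(list(pa, pb), "bridge"), "dropped 1 rows")
  expect_equal(nrow(j$rows), 3L)
  expect_equal(unname(attr(j, "bridge_dropped")[["no_bridge"]]), 1)
  # a plex without the bridge channel is an error
  nob <- reporter_matrix(base, channels = data.frame(label = c("s1", "s2")))
  expect_error(bridge_normalize(list(nob), "bridge"), "exactly one channel")
})

test_that("phosphosite intensities are rescaled by the proteome total-sum factors", {
  set.seed(4)
  m <- matrix(2^rnorm(40, 18, 1), 10, 4,
              dimnames = list(NULL, paste0("ch", 1:4)))
  rep1 <- total_sum_normalize(m)$ # factors all 1 after normalizing twice
    report
  sites <- matrix(2^rnorm(20, 14, 1), 5, 4, dimnames = list(NULL, paste0("ch", 1:4)))
  # identity when factors are all 1
  unit <- rep1; unit$factors[] <- 1
  expect_equal(normalize_phospho_by_proteome(sites, unit), sites)
  # a factor of 2 on one channel doubles that site channel
  f2 <- unit; f2$factors[["ch3"]] <- 2
  out <- normalize_phospho_by_proteome(sites, f2)
  expect_equal(out[, "ch3"], sites[, "ch3"] * 2)
  expect_equal(out[, "ch1"], sites[, "ch1"])
  # channel mismatch errors
  bad <- sites; colnames(bad) <- paste0("x", 1:4)
  expect_error(normalize_phospho_by_proteome(bad, unit), "do not match")
})
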