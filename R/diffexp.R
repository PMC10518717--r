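#' S0-moderated two-sample t statistic
#'
#' The SAM-style relative difference: `d = (mean(a) - mean(b)) / (s + s0)`,
#' where `s` is the pooled two-sample standard error and `s0` a nonnegative
#' fudge constant that damps the statistic for low-variance rows. With
#' `s0 = 0` this is the ordinary pooled-variance (Student) t statistic.
#'
#' @param a,b numeric vectors (log2 intensities) for the two groups; each
#'   needs at least two finite values, otherwise the row is untestable and
#'   `NA`s are returned.
#' @param s0 nonnegative fudge constant.
#' @return A list with elements `d`, `log2fc` (`mean(a) - mean(b)`) and `s`.
#' @export
#' @examples
#' s0_t_statistic(c(2, 2, 2), c(1, 1, 1), s0 = 0.5)  # d = 2
s0_t_statistic <- function(a, b, s0 = 0) {
  s0 <- .check_num(s0, "s0", min = 0)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L)
    return(list(d = NA_real_, log2fc = NA_real_, s = NA_real_))
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  s <- sqrt(sp2 * (1 / na + 1 / nb))
  fc <- mean(a) - mean(b)
  list(d = fc / (s + s0), log2fc = fc, s = s)
}

# Vectorized row-wise two-group statistics on a rows x samples matrix.
# Returns means, log2 fc, pooled SE s, d (with s0), Student p, testable flag.
.row_stats <- function(X, idx1, idx2, s0 = 0) {
  g1 <- X[, idx1, drop = FALSE]; g2 <- X[, idx2, drop = FALSE]
  n1 <- rowSums(is.finite(g1)); n2 <- rowSums(is.finite(g2))
  m1 <- rowMeans(g1, na.rm = TRUE); m2 <- rowMeans(g2, na.rm = TRUE)
  ss1 <- rowSums(g1^2, na.rm = TRUE) - n1 * m1^2
  ss2 <- rowSums(g2^2, na.rm = TRUE) - n2 * m2^2
  ss1 <- pmax(ss1, 0); ss2 <- pmax(ss2, 0)
  df <- n1 + n2 - 2
  testable <- n1 >= 2 & n2 >= 2
  sp2 <- ifelse(df > 0, (ss1 + ss2) / df, NA_real_)
  s <- sqrt(sp2 * (1 / n1 + 1 / n2))
  fc <- m1 - m2
  d <- fc / (s + s0)
  t0 <- ifelse(s > 0, fc / s, ifelse(fc == 0, 0, Inf * sign(fc)))
  p <- 2 * pt(-abs(t0), df)
  p[s == 0 & fc == 0] <- 1
  p[s == 0 & fc != 0] <- 0
  d[!testable] <- NA_real_; p[!testable] <- NA_real_
  s[!testable] <- NA_real_; fc[!testable] <- NA_real_
  list(mean1 = m1, mean2 = m2, log2fc = fc, s = s, d = d, p = p,
       testable = testable)
}

.label_idx <- function(labels) {
  labels <- as.character(labels)
  lv <- unique(labels[!is.na(labels)])
  if (length(lv) != 2L) .stopf("exactly two groups required (found: %s)",
                               paste(lv, collapse = ", "))
  list(idx1 = which(labels == lv[1L]), idx2 = which(labels == lv[2L]), levels = lv)
}

#' Estimate the S0 fudge constant (Tusher procedure)
#'
#' Candidate `s0` values are percentiles of the distribution of the pooled
#' standard errors `s`. For each candidate, the moderated statistics
#' `d = fc / (s + s0)` are computed, rows are binned into windows of `s`, and
#' the median absolute deviation (MAD) of `d` is computed per window. The
#' chosen `s0` minimizes the coefficient of variation of these window MADs,
#' i.e. it makes the spread of `d` as independent of `s` as possible.
#'
#' @param x log2 intensity matrix (rows x samples) or [reporter_matrix]
#'   holding log2 values.
#' @param labels two-level group labels, one per column.
#' @param probs percentile grid of `s` used as `s0` candidates.
#' @param n_windows number of `s` windows for the MAD computation.
#' @return The selected `s0` (a single nonnegative number).
#' @export
estimate_s0 <- function(x, labels, probs = seq(0, 1, by = 0.05), n_windows = 25L) {
  X <- .get_mat(x)
  li <- .label_idx(labels)
  st <- .row_stats(X, li$idx1, li$idx2, s0 = 0)
  ok <- st$testable & is.finite(st$s)
  s <- st$s[ok]; fc <- st$log2fc[ok]
  if (length(s) < 10L) .stopf("too few testable rows to estimate s0")
  cand <- unique(as.numeric(quantile(s, probs)))
  if (max(s) - min(s) < .Machine$double.eps^0.5 * max(s, 1)) {
    return(min(cand))  # s constant: all candidates equivalent, return smallest
  }
  n_windows <- min(n_windows, max(2L, floor(length(s) / 20)))
  win <- cut(rank(s, ties.method = "first"), breaks = n_windows, labels = FALSE)
  cv <- vapply(cand, function(s0) {
    d <- fc / (s + s0)
    mads <- tapply(d, win, mad)
    mu <- mean(mads)
    if (!is.finite(mu) || mu == 0) return(NA_real_)
    sd(mads) / mu
  }, numeric(1))
  if (all(!is.finite(cv))) {
    fb <- median(s)
    message(sprintf("estimate_s0: degenerate s distribution, falling back to median(s) = %.4g", fb))
    return(fb)
  }
  cand[which.min(cv)]
}

#' Differential-testing configuration
#'
#' @param alpha significance level for the FDR (fraction in (0,1)).
#' @param s0 the S0 fudge constant; a nonnegative number or `"auto"` to
#'   estimate it with [estimate_s0()].
#' @param n_permutations number of balanced label shuffles for the
#'   permutation FDR (at least 1; if it meets or exceeds the number of
#'   distinct shuffles these are enumerated exactly).
#' @param seed integer seed for the permutation draw.
#' @param correction `"permutation"` or `"benjamini-hochberg"`.
#' @return A `test_config` list.
#' @export
test_config <- function(alpha = 0.05, s0 = 0,
                        n_permutations = 250L, seed = 1L,
                        correction = c("permutation", "benjamini-hochberg")) {
  correction <- match.arg(correction)
  if (!identical(s0, "auto")) s0 <- .check_num(s0, "s0", min = 0)
  stopifnot(alpha > 0, alpha < 1)
  structure(list(alpha = alpha, s0 = s0,
                 n_permutations = .check_count(n_permutations, "n_permutations", min = 1L),
                 seed = .check_count(seed, "seed"),
                 correction = correction),
            class = "test_config")
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' @param pvalues numeric vector of p-values in \[0, 1\] (no non-finite
#'   values allowed).
#' @return Vector of BH-adjusted q-values, monotone nondecreasing in p.
#' @export
bh_fdr <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    .stopf("p-values must be finite and in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

# All balanced group-1 index sets (columns), or a seeded random sample of
# shuffles when full enumeration is infeasible/unnecessary.
.perm_sets <- function(n, n1, n_permutations, seed) {
  total <- choose(n, n1)
  if (total <= n_permutations) {
    return(list(sets = combn(n, n1), exhaustive = TRUE))
  }
  set.seed(seed)
  sets <- replicate(n_permutations, sort(sample.int(n, n1)))
  list(sets = sets, exhaustive = FALSE)
}

#' Permutation-based FDR for two-group S0-moderated tests
#'
#' Computes the observed `|d|` per row; recomputes `|d|` under balanced label
#' shuffles (all distinct shuffles are enumerated when `n_permutations`
#' covers them, otherwise a seeded random sample is used); for each threshold
#' `delta` on `|d|`, estimates `FDR(delta) = mean permuted count of |d| >=
#' delta / observed count of |d| >= delta`, capped at 1. The per-row q-value
#' is the minimal FDR over thresholds at or below that row's `|d|` (monotone
#' by construction), and rows are significant when `q <= alpha`, i.e. at the
#' largest threshold set with FDR below `alpha`. Rows with `|d|` exactly at a
#' threshold are included (`>=`).
#'
#' @inheritParams estimate_s0
#' @param config a [test_config()]; `correction` is ignored (this *is* the
#'   permutation mode).
#' @return A data frame with columns `id`, `log2fc`, `s`, `d`, `q`,
#'   `significant`, plus attribute `"exhaustive"`.
#' @export
permutation_fdr <- function(x, labels, config = test_config()) {
  X <- .get_mat(x)
  li <- .label_idx(labels)
  n1 <- length(li$idx1); n2 <- length(li$idx2)
  if (n1 < 2L || n2 < 2L) .stopf("each group needs at least two samples")
  s0 <- config$s0
  if (identical(s0, "auto")) s0 <- estimate_s0(X, labels)
  cols <- c(li$idx1, li$idx2)
  Xs <- X[, cols, drop = FALSE]
  obs <- .row_stats(Xs, seq_len(n1), n1 + seq_len(n2), s0 = s0)
  absd <- abs(obs$d)

  ps <- .perm_sets(n1 + n2, n1, config$n_permutations, config$seed)
  n_perm <- ncol(ps$sets)
  if (ps$exhaustive && n_perm < config$n_permutations)
    message(sprintf("permutation_fdr: enumerating all %d distinct balanced shuffles", n_perm))
  all_idx <- seq_len(n1 + n2)
  perm_absd <- matrix(NA_real_, nrow = nrow(Xs), ncol = n_perm)
  for (k in seq_len(n_perm)) {
    g1 <- ps$sets[, k]
    st <- .row_stats(Xs, g1, setdiff(all_idx, g1), s0 = s0)
    perm_absd[, k] <- abs(st$d)
  }

  thr <- sort(unique(absd[is.finite(absd)]))
  q <- rep(NA_real_, length(absd))
  if (length(thr)) {
    pooled <- sort(perm_absd[is.finite(perm_absd)])
    obs_sorted <- sort(absd[is.finite(absd)])
    n_obs_ge <- length(obs_sorted) - findInterval(thr, obs_sorted, left.open = TRUE)
    n_perm_ge <- (length(pooled) - findInterval(thr, pooled, left.open = TRUE)) / n_perm
    fdr <- pmin(1, n_perm_ge / n_obs_ge)
    # q at threshold t_k = minimal FDR over thresholds <= t_k
    qthr <- cummin(fdr)
    q <- qthr[match(absd, thr)]
  }
  sig <- !is.na(q) & q <= config$alpha
  out <- data.frame(id = rownames(Xs) %||% as.character(seq_len(nrow(Xs))),
                    log2fc = obs$log2fc, s = obs$s, d = obs$d, q = q,
                    significant = sig, stringsAsFactors = FALSE)
  attr(out, "exhaustive") <- ps$exhaustive
  attr(out, "s0") <- s0
  out
}

#' Two-group differential expression with FDR control
#'
#' Full two-group analysis of a (filtered, normalized, log2) reporter
#' matrix: per-row log2 fold change, pooled standard error, S0-moderated
#' statistic `d`, Student-t p-value, and either permutation-based or
#' Benjamini-Hochberg FDR. Rows are labeled with fold-change bands
#' (`|log2FC|` in \[1, 2\] and > 2, closed at 1) matching the volcano-plot
#' band counts.
#'
#' @inheritParams estimate_s0
#' @param labels two-level group labels per column; defaults to the channel
#'   `condition` metadata for a [reporter_matrix].
#' @param config a [test_config()].
#' @param log2_transform set `TRUE` if `x` holds raw intensities that still
#'   need log2 transformation.
#' @return A `diffexp_result` data frame with columns `id`, `mean1`, `mean2`,
#'   `log2fc`, `s`, `d`, `p`, `q`, `significant`, `band`, and attributes
#'   `band_counts`, `s0`, `groups`.
#' @export
differential_expression <- function(x, labels = NULL, config = test_config(),
                                    log2_transform = FALSE) {
  X <- .get_mat(x)
  if (is.null(labels)) {
    if (!inherits(x, "reporter_matrix"))
      .stopf("'labels' required for a plain matrix")
    labels <- x$channels$condition
  }
  if (log2_transform) X <- log2(X)
  li <- .label_idx(labels)
  s0 <- config$s0
  if (identical(s0, "auto")) s0 <- estimate_s0(X, labels)
  obs <- .row_stats(X, li$idx1, li$idx2, s0 = s0)
  if (config$correction == "permutation") {
    pf <- permutation_fdr(X, labels,
                          test_config(alpha = config$alpha, s0 = s0,
                                      n_permutations = config$n_permutations,
                                      seed = config$seed))
    q <- pf$q; sig <- pf$significant
  } else {
    q <- rep(NA_real_, nrow(X))
    ok <- obs$testable
    q[ok] <- bh_fdr(obs$p[ok])
    sig <- !is.na(q) & q <= config$alpha
  }
  afc <- abs(obs$log2fc)
  band <- ifelse(!is.finite(afc), NA_character_,
                 ifelse(afc > 2, ">2", ifelse(afc >= 1, "1-2", "none")))
  out <- data.frame(id = rownames(X) %||% as.character(seq_len(nrow(X))),
                    mean1 = obs$mean1, mean2 = obs$mean2, log2fc = obs$log2fc,
                    s = obs$s, d = obs$d, p = obs$p, q = q, significant = sig,
                    band = band, stringsAsFactors = FALSE)
  class(out) <- c("diffexp_result", "data.frame")
  attr(out, "band_counts") <- table(factor(band, levels = c("none", "1-2", ">2")))
  attr(out, "s0") <- s0
  attr(out, "groups") <- li$levels
  out
}

#' @export
print.diffexp_result <- function(x, ...) {
  g <- attr(x, "groups")
  cat(sprintf("diffexp_result: %d rows, groups %s vs %s, s0 = %.4g\n",
              nrow(x), g[1], g[2], attr(x, "s0")))
  cat(sprintf("  significant: %d; fold-change bands: |FC| 1-2: %d, >2: %d\n",
              sum(x$significant, na.rm = TRUE),
              attr(x, "band_counts")[["1-2"]], attr(x, "band_counts")[[">2"]]))
  NextMethod()
}
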