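#' Pool per-solvent soluble-fraction intensities
#'
#' Equal-amount pooling of the soluble fractions across the solvent gradient:
#' the pooled intensity is the mean of the per-solvent-step intensities on a
#' common grid. This mirrors the physical pooling of equal amounts of each
#' soluble fraction before MS; it is used by the simulator and for users
#' supplying per-fraction data (the assay itself pools before measurement,
#' so pooled intensity is the primary observable).
#'
#' @param fractions numeric matrix, rows = proteins, columns = solvent steps
#'   (one value per step).
#' @param solvent_grid solvent percentages labelling the columns; must match
#'   `ncol(fractions)`.
#' @return Numeric vector of pooled intensities (one per protein).
#' @export
pool_soluble_fractions <- function(fractions, solvent_grid = c(8, 10, 12, 14, 16, 18, 20, 22)) {
  fractions <- as.matrix(fractions)
  if (ncol(fractions) != length(solvent_grid))
    .stopf("fractions have %d columns but the solvent grid has %d steps",
           ncol(fractions), length(solvent_grid))
  rowMeans(fractions)
}

#' Stabilization analysis of pooled SIP intensities
#'
#' For each requested contrast (a treatment condition vs its reference, e.g.
#' each active-compound dose vs the matched inactive-analog dose), performs a
#' two-sample Student t test on log2 pooled intensities per protein,
#' Benjamini-Hochberg correction across proteins within the contrast, and
#' flags significant stabilization (`q < alpha` and positive log2 ratio) or
#' destabilization (negative ratio). The input is expected to be filtered
#' (minimum two unique peptides) and median-centered; intensities are
#' log2-transformed internally.
#'
#' @param x a [reporter_matrix] of pooled intensities (raw scale) with
#'   channel `condition` metadata, or a plain matrix plus `conditions`.
#' @param contrasts list of 2-element character vectors
#'   `c(treatment, reference)`; default: every non-reference condition vs
#'   `reference`.
#' @param conditions condition label per channel (defaults to channel
#'   metadata).
#' @param reference reference condition used to build default contrasts.
#' @param alpha FDR level (default 0.05).
#' @param s0 optional S0 fudge constant added to the t-statistic denominator
#'   for the reported `d` (the p-value always uses the ordinary Student t).
#' @return A `stabilization_result` data frame with columns `contrast`, `id`,
#'   `mean_treatment`, `mean_reference` (log2), `log2_ratio`, `d`, `p`, `q`,
#'   `significant`, `direction`. Contrasts with fewer than two replicates on
#'   either side are skipped with a warning.
#' @export
stabilization_analysis <- function(x, contrasts = NULL, conditions = NULL,
                                   reference = NULL, alpha = 0.05, s0 = 0) {
  X <- .get_mat(x)
  if (is.null(conditions)) {
    if (!inherits(x, "reporter_matrix")) .stopf("'conditions' required for a plain matrix")
    conditions <- x$channels$condition
  }
  stopifnot(length(conditions) == ncol(X))
  L <- log2(X)
  if (is.null(contrasts)) {
    if (is.null(reference)) .stopf("either 'contrasts' or 'reference' must be given")
    if (!reference %in% conditions) .stopf("reference condition '%s' not present", reference)
    contrasts <- lapply(setdiff(unique(conditions), reference),
                        function(tr) c(tr, reference))
  }
  res <- list()
  for (ct in contrasts) {
    tr <- ct[[1L]]; ref <- ct[[2L]]
    it <- which(conditions == tr); ir <- which(conditions == ref)
    if (length(it) == 0L || length(ir) == 0L)
      .stopf("contrast %s vs %s: condition missing from the data", tr, ref)
    if (length(it) < 2L || length(ir) < 2L) {
      .warnf("contrast %s vs %s skipped: fewer than two replicates in a condition", tr, ref)
      next
    }
    st <- .row_stats(L, it, ir, s0 = s0)
    q <- rep(NA_real_, nrow(L))
    q[st$testable] <- bh_fdr(st$p[st$testable])
    sig <- !is.na(q) & q < alpha
    res[[paste(tr, "vs", ref)]] <- data.frame(
      contrast = paste(tr, "vs", ref),
      id = rownames(L) %||% as.character(seq_len(nrow(L))),
      mean_treatment = st$mean1, mean_reference = st$mean2,
      log2_ratio = st$log2fc, d = st$d, p = st$p, q = q,
      significant = sig,
      direction = ifelse(!sig, "ns",
                         ifelse(st$log2fc > 0, "stabilized", "destabilized")),
      stringsAsFactors = FALSE)
  }
  if (!length(res)) .stopf("no testable contrasts")
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("stabilization_result", "data.frame")
  attr(out, "alpha") <- alpha
  out
}

#' Dose-trend summary of stabilization
#'
#' For two doses of the active compound relative to a reference (inactive
#' analog) condition, computes per protein the ratio of the treated replicate
#' median to the reference replicate median on the raw intensity scale, the
#' range (min, max) of per-replicate ratios (each treated replicate over the
#' reference median), and a dose-dependence flag:
#' `ratio(high) > ratio(low) > 1`.
#'
#' @inheritParams stabilization_analysis
#' @param dose_low,dose_high condition labels of the two active-compound
#'   doses.
#' @param reference condition label of the reference (inactive compound).
#' @return Data frame with one row per protein: `ratio_low`, `low_min`,
#'   `low_max`, `ratio_high`, `high_min`, `high_max`, `dose_dependent`.
#' @export
dose_trend <- function(x, dose_low, dose_high, reference, conditions = NULL) {
  X <- .get_mat(x)
  if (is.null(conditions)) {
    if (!inherits(x, "reporter_matrix")) .stopf("'conditions' required for a plain matrix")
    conditions <- x$channels$condition
  }
  for (cc in c(dose_low, dose_high, reference))
    if (!cc %in% conditions) .stopf("condition '%s' not present", cc)
  ref_med <- apply(X[, conditions == reference, drop = FALSE], 1L, median, na.rm = TRUE)
  if (any(!is.finite(ref_med) | ref_med == 0))
    .stopf("zero or missing reference median for %d protein(s)",
           sum(!is.finite(ref_med) | ref_med == 0))
  one_dose <- function(cond) {
    reps <- X[, conditions == cond, drop = FALSE] / ref_med
    list(ratio = apply(reps, 1L, median, na.rm = TRUE),
         min = apply(reps, 1L, min, na.rm = TRUE),
         max = apply(reps, 1L, max, na.rm = TRUE))
  }
  lo <- one_dose(dose_low); hi <- one_dose(dose_high)
  data.frame(id = rownames(X) %||% as.character(seq_len(nrow(X))),
             ratio_low = lo$ratio, low_min = lo$min, low_max = lo$max,
             ratio_high = hi$ratio, high_min = hi$min, high_max = hi$max,
             dose_dependent = hi$ratio > lo$ratio & lo$ratio > 1,
             stringsAsFactors = FALSE)
}
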