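#' @name tmt-normalization
#' @title TMT reporter-intensity normalization
#'
#' @description Four normalization procedures for reporter-intensity
#' matrices, operating on raw (unlogged) intensities:
#'
#' * `total_sum_normalize()` scales every channel so its intensity total
#'   equals the mean of the original channel totals. Used for the
#'   proteome-profiling plexes.
#' * `median_center()` scales every channel so its median equals the grand
#'   median of all intensities (computed before centering); optionally
#'   additive on the log2 scale. Used for the compound-treatment and SIP
#'   plexes.
#' * `bridge_normalize()` divides, within each plex, every protein by its
#'   intensity in that plex's common bridge channel (the untreated
#'   reference), then joins plexes on row id. A global per-plex batch factor
#'   cancels exactly in these ratios.
#' * `normalize_phospho_by_proteome()` applies the full-proteome total-sum
#'   scale factors to a phosphosite matrix, so that site fold changes are
#'   corrected for proteome loading.
#'
#' The target constants (mean of sums, grand median) only fix an overall
#' scale; any positive target yields identical downstream ratios.
#'
#' @param x a [reporter_matrix] (or plain numeric matrix).
#' @return For the two channel-scaling functions, a list with elements
#'   `matrix` (same class as the input) and `report` (a
#'   `normalization_report`: method name and named per-channel scale
#'   factors). `bridge_normalize()` returns a single joined
#'   [reporter_matrix] of bridge ratios. `normalize_phospho_by_proteome()`
#'   returns the rescaled site matrix.
NULL

.get_mat <- function(x) if (inherits(x, "reporter_matrix")) x$intensity else as.matrix(x)

.set_mat <- function(x, m) {
  if (inherits(x, "reporter_matrix")) { x$intensity <- m; x } else m
}

.norm_report <- function(method, factors, bridge = NULL) {
  if (any(!is.finite(factors) | factors <= 0))
    .stopf("%s: scale factors must be positive and finite", method)
  structure(list(method = method, factors = factors, bridge = bridge),
            class = "normalization_report")
}

#' @export
print.normalization_report <- function(x, ...) {
  cat(sprintf("normalization_report: %s\n", x$method))
  print(round(x$factors, 4))
  invisible(x)
}

.check_channels_usable <- function(m, what) {
  ok <- colSums(is.finite(m)) > 0
  if (!all(ok))
    .stopf("%s: channel(s) with no finite values: %s", what,
           paste(colnames(m)[!ok], collapse = ", "))
}

#' @rdname tmt-normalization
#' @export
total_sum_normalize <- function(x) {
  m <- .get_mat(x)
  .check_channels_usable(m, "total_sum_normalize")
  sums <- colSums(m, na.rm = TRUE)
  factors <- mean(sums) / sums
  out <- sweep(m, 2L, factors, `*`)
  list(matrix = .set_mat(x, out),
       report = .norm_report("total_sum", factors))
}

#' @rdname tmt-normalization
#' @param on_log if `TRUE`, median-center additively on the log2 scale
#'   (equivalent to multiplicative centering of geometric medians on the raw
#'   scale) instead of multiplicatively on raw intensities.
#' @export
median_center <- function(x, on_log = FALSE) {
  m <- .get_mat(x)
  .check_channels_usable(m, "median_center")
  if (on_log) {
    lm_ <- log2(m)
    meds <- apply(lm_, 2L, median, na.rm = TRUE)
    grand <- median(lm_[is.finite(lm_)])
    factors <- 2^(grand - meds)
  } else {
    meds <- apply(m, 2L, median, na.rm = TRUE)
    grand <- median(m[is.finite(m)])
    factors <- grand / meds
  }
  out <- sweep(m, 2L, factors, `*`)
  list(matrix = .set_mat(x, out),
       report = .norm_report("median_center", factors))
}

#' @rdname tmt-normalization
#' @param plexes a list of [reporter_matrix] objects, one per TMT plex; each
#'   must contain exactly one channel labeled `bridge_label`.
#' @param bridge_label channel label of the common bridge (untreated
#'   reference) channel.
#' @export
bridge_normalize <- function(plexes, bridge_label = "bridge") {
  stopifnot(is.list(plexes), length(plexes) >= 1L)
  ratio_plex <- list()
  for (k in seq_along(plexes)) {
    p <- plexes[[k]]
    stopifnot(inherits(p, "reporter_matrix"))
    bi <- which(p$channels$label == bridge_label)
    if (length(bi) != 1L)
      .stopf("plex %d must contain exactly one channel labeled '%s' (found %d)",
             k, bridge_label, length(bi))
    bridge <- p$intensity[, bi]
    keep <- is.finite(bridge) & bridge > 0
    ratios <- p$intensity[keep, -bi, drop = FALSE] / bridge[keep]
    ch <- p$channels[-bi, , drop = FALSE]
    ch$label <- make.unique(paste0("plex", p$channels$plex[-bi], ".", ch$label))
    ratio_plex[[k]] <- list(ratios = ratios, rows = p$rows[keep, , drop = FALSE],
                            channels = ch, dropped = sum(!keep))
  }
  ids <- Reduce(intersect, lapply(ratio_plex, function(z) rownames(z$ratios)))
  dropped_join <- sum(vapply(ratio_plex, function(z) nrow(z$ratios), 0)) -
    length(ids) * length(ratio_plex)
  mat <- do.call(cbind, lapply(ratio_plex, function(z) z$ratios[ids, , drop = FALSE]))
  channels <- do.call(rbind, lapply(ratio_plex, `[[`, "channels"))
  rows <- ratio_plex[[1L]]$rows[match(ids, ratio_plex[[1L]]$rows$id), , drop = FALSE]
  n_bridge_dropped <- sum(vapply(ratio_plex, `[[`, 0, "dropped"))
  if (n_bridge_dropped + dropped_join > 0)
    message(sprintf(
      "bridge_normalize: dropped %d rows without valid bridge value and %d rows absent from some plex",
      n_bridge_dropped, dropped_join))
  out <- reporter_matrix(mat, rows = rows, channels = channels)
  attr(out, "bridge_dropped") <- c(no_bridge = n_bridge_dropped, join = dropped_join)
  out
}

#' @rdname tmt-normalization
#' @param sites a [reporter_matrix] of phosphosite intensities whose channel
#'   labels match the proteome channels.
#' @param proteome_report the `normalization_report` returned by
#'   [total_sum_normalize()] on the matching full-proteome matrix.
#' @export
normalize_phospho_by_proteome <- function(sites, proteome_report) {
  stopifnot(inherits(proteome_report, "normalization_report"))
  m <- .get_mat(sites)
  f <- proteome_report$factors
  if (!setequal(colnames(m), names(f)) || ncol(m) != length(f))
    .stopf("site channels do not match proteome channels (%s vs %s)",
           paste(colnames(m), collapse = ","), paste(names(f), collapse = ","))
  out <- sweep(m, 2L, f[colnames(m)], `*`)
  .set_mat(sites, out)
}
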