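#' Percent effect relative to neutral and stimulator controls
#'
#' Rescales a raw well readout so the median of the neutral (DMSO) control
#' wells defines 0% and the median of the stimulator control wells (mIL-2 in
#' the mouse coculture assay, or the no-MDSC wells in the human assay)
#' defines 100%:
#' `100 * (raw - median(neutral)) / (median(stimulator) - median(neutral))`.
#' Medians are used as the control aggregator for robustness to edge-well
#' outliers. Affine-invariant: rescaling all raw signals by any positive
#' affine map leaves the result unchanged.
#'
#' @param raw numeric vector of raw readouts to convert.
#' @param neutral_wells,stimulator_wells raw readouts of the control wells
#'   (at least 2 each).
#' @return Percent effects (same length as `raw`).
#' @export
percent_effect <- function(raw, neutral_wells, stimulator_wells) {
  if (length(neutral_wells) < 2L || length(stimulator_wells) < 2L)
    .stopf("at least 2 wells required per control role")
  mn <- median(neutral_wells); ms <- median(stimulator_wells)
  if (ms == mn) .stopf("control medians are equal; percent effect undefined")
  100 * (raw - mn) / (ms - mn)
}

#' Normalize a plate readout table to per-compound percent effects
#'
#' @param plate data frame with columns `well`, `role` (one of `compound`,
#'   `neutral`, `stimulator`), `compound` (id, for compound wells) and the
#'   two readout columns named in `readouts`.
#' @param readouts names of the two readout columns.
#' @return Data frame with one row per compound and percent-effect columns
#'   `effect_<readout>` (mean over replicate wells).
#' @export
normalize_plate <- function(plate, readouts = c("prolif", "ifng")) {
  stopifnot(all(c("well", "role", "compound") %in% names(plate)),
            all(readouts %in% names(plate)))
  if (!all(plate$role %in% c("compound", "neutral", "stimulator")))
    .stopf("unknown well role(s): %s",
           paste(setdiff(plate$role, c("compound", "neutral", "stimulator")), collapse = ", "))
  cmp <- plate[plate$role == "compound", , drop = FALSE]
  out <- data.frame(compound = unique(cmp$compound), stringsAsFactors = FALSE)
  for (r in readouts) {
    pe <- percent_effect(cmp[[r]],
                         plate[[r]][plate$role == "neutral"],
                         plate[[r]][plate$role == "stimulator"])
    out[[paste0("effect_", r)]] <-
      as.numeric(tapply(pe, cmp$compound, mean)[out$compound])
  }
  out
}

#' Call screen hits from percent effects
#'
#' A compound is a hit when it shows a percent effect strictly greater than
#' `threshold` in at least one of the two readouts. Compounds with a missing
#' readout are flagged untestable (not hits).
#'
#' @param effects data frame with `compound` and two `effect_*` columns (as
#'   from [normalize_plate()]).
#' @param threshold hit threshold in percent (strict `>`; default 50).
#' @return The input with logical columns `hit` and `untestable` appended.
#' @export
call_hits <- function(effects, threshold = 50) {
  ec <- grep("^effect_", names(effects), value = TRUE)
  if (length(ec) < 1L) .stopf("no effect_* columns found")
  em <- as.matrix(effects[, ec, drop = FALSE])
  untestable <- rowSums(is.na(em)) > 0
  hit <- apply(em > threshold, 1L, any, na.rm = TRUE) & !untestable
  effects$hit <- hit
  effects$untestable <- untestable
  attr(effects, "threshold") <- threshold
  effects
}

#' Counter-screen validation of hits
#'
#' Hits are validated when the compound shows no direct effect on T cells in
#' the counter assay (T-cell activity measured without MDSC): both
#' counter-screen percent effects must stay below `inactivity_threshold`.
#' Hits without counter-screen data are excluded (validated = `NA`, logged).
#'
#' @param hits output of [call_hits()].
#' @param tcell_only_effects data frame with `compound` and the counter
#'   `effect_*` columns.
#' @param inactivity_threshold maximum counter-screen percent effect for a
#'   compound to count as inactive on T cells (default 20).
#' @return `hits` with counter-effect columns (`counter_*`) and a
#'   `validated` column appended.
#' @export
counter_screen_filter <- function(hits, tcell_only_effects, inactivity_threshold = 20) {
  stopifnot("compound" %in% names(tcell_only_effects))
  ec <- grep("^effect_", names(tcell_only_effects), value = TRUE)
  idx <- match(hits$compound, tcell_only_effects$compound)
  cm <- as.matrix(tcell_only_effects[idx, ec, drop = FALSE])
  colnames(cm) <- sub("^effect_", "counter_", ec)
  inactive <- rowSums(cm >= inactivity_threshold) == 0  # NA if any counter missing
  validated <- hits$hit & inactive
  validated[!hits$hit] <- FALSE        # a non-hit is never validated
  n_missing <- sum(hits$hit & is.na(validated))
  if (n_missing > 0)
    message(sprintf("counter_screen_filter: %d hit(s) lack counter-screen data and were excluded", n_missing))
  out <- cbind(hits, as.data.frame(cm))
  out$validated <- validated
  attr(out, "inactivity_threshold") <- inactivity_threshold
  out
}

.logistic4 <- function(lx, bottom, top, lec50, hill) {
  bottom + (top - bottom) / (1 + 10^(hill * (lec50 - lx)))
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares 4PL fit (bottom, top, EC50, Hill slope) on the log10
#' concentration axis with box-bounded parameters (Levenberg-Marquardt via
#' \pkg{minpack.lm}). The default bounds keep percent-effect fits plausible
#' (bottom >= -20%, top <= 120%). Negative Hill slopes (monotone-decreasing
#' data) are allowed. A fitted span below `min_span` classifies the compound
#' as inactive (flat response).
#'
#' @param concentrations dose vector (molar; > 0; at least 4 distinct).
#' @param responses percent effects at those doses.
#' @param bottom_min,top_max parameter bounds.
#' @param min_span minimum fitted span `|top - bottom|` (percent) for an
#'   active classification.
#' @return An object of class `dose_response_fit` with elements
#'   `parameters` (bottom, top, ec50, hill), `ec50`, `ec50_relative`
#'   (concentration at 50% of the fitted span; equals `ec50` for a 4PL),
#'   `converged`, `active`, `extrapolated`, `r2`, `data`.
#' @export
#' @examples
#' doses <- 10^seq(-8, -4, length.out = 8)
#' y <- 100 / (1 + (2.6e-6 / doses))
#' fit <- fit_dose_response(doses, y)
#' coef(fit)
fit_dose_response <- function(concentrations, responses,
                              bottom_min = -20, top_max = 120, min_span = 20) {
  keep <- is.finite(concentrations) & is.finite(responses) & concentrations > 0
  x <- concentrations[keep]; y <- responses[keep]
  if (length(unique(x)) < 4L) .stopf("at least 4 distinct concentrations required")
  lx <- log10(x)
  hill0 <- if (cor(lx, y) >= 0) 1 else -1
  start <- list(bottom = max(bottom_min, min(y)), top = min(top_max, max(y)),
                lec50 = median(lx), hill = hill0)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ .logistic4(lx, bottom, top, lec50, hill),
                      start = start,
                      lower = c(bottom = bottom_min, top = -Inf,
                                lec50 = min(lx) - 3, hill = -10),
                      upper = c(bottom = Inf, top = top_max,
                                lec50 = max(lx) + 3, hill = 10),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    out <- list(parameters = c(bottom = NA_real_, top = NA_real_,
                               ec50 = NA_real_, hill = NA_real_),
                ec50 = NA_real_, ec50_relative = NA_real_, converged = FALSE,
                active = FALSE, extrapolated = NA, r2 = NA_real_,
                data = data.frame(concentration = x, response = y))
    return(structure(out, class = "dose_response_fit"))
  }
  cf <- coef(fit)
  ec50 <- 10^cf[["lec50"]]
  span <- abs(cf[["top"]] - cf[["bottom"]])
  r2 <- 1 - sum(resid(fit)^2) / max(sum((y - mean(y))^2), .Machine$double.eps)
  out <- list(parameters = c(bottom = cf[["bottom"]], top = cf[["top"]],
                             ec50 = ec50, hill = cf[["hill"]]),
              ec50 = ec50, ec50_relative = ec50,
              converged = TRUE, active = span >= min_span,
              extrapolated = ec50 < min(x) | ec50 > max(x), r2 = r2,
              data = data.frame(concentration = x, response = y))
  structure(out, class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (!x$converged) {
    cat("dose_response_fit: did not converge\n")
  } else {
    p <- x$parameters
    cat(sprintf(
      "dose_response_fit: EC50 = %.3g M (%s), bottom %.1f, top %.1f, hill %.2f, R2 %.3f\n",
      x$ec50, if (x$active) "active" else "inactive (span below minimum)",
      p[["bottom"]], p[["top"]], p[["hill"]], x$r2))
    if (isTRUE(x$extrapolated)) cat("  note: EC50 outside the tested range (extrapolated)\n")
  }
  invisible(x)
}

#' @export
coef.dose_response_fit <- function(object, ...) object$parameters

#' @export
predict.dose_response_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$concentration else
    if (is.list(newdata)) newdata$concentration else newdata
  p <- object$parameters
  .logistic4(log10(conc), p[["bottom"]], p[["top"]], log10(p[["ec50"]]), p[["hill"]])
}

#' @export
plot.dose_response_fit <- function(x, ...) {
  plot(x$data$concentration, x$data$response, log = "x",
       xlab = "concentration (M)", ylab = "% effect", ...)
  if (x$converged) {
    grid_x <- 10^seq(log10(min(x$data$concentration)),
                     log10(max(x$data$concentration)), length.out = 100)
    graphics::lines(grid_x, predict(x, grid_x))
  }
  invisible(x)
}

#' Bin per-donor percent effects into response categories
#'
#' Donor responses are categorized as `strong` (effect > 40%), `mild`
#' (0 < effect <= 40%, closed upper boundary) or `none` (effect <= 0).
#'
#' @param effects numeric vector of per-donor percent effects.
#' @return A list with `category` (factor per donor) and `counts` (named
#'   vector over `none`, `mild`, `strong`).
#' @export
bin_donor_effects <- function(effects) {
  stopifnot(is.numeric(effects))
  category <- factor(ifelse(effects > 40, "strong",
                            ifelse(effects > 0, "mild", "none")),
                     levels = c("none", "mild", "strong"))
  list(category = category, counts = table(category))
}
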