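#' Construct a competition pulldown dose series
#'
#' One protein's intensities across an inhibitor dose ladder (vehicle first)
#' from a competition pulldown, plus the vehicle PD/PDPD intensity pair from
#' two consecutive pulldowns used to estimate bead-mediated depletion, and
#' identification evidence counts.
#'
#' @param protein protein id.
#' @param doses dose ladder in molar; first entry must be 0 (vehicle) and the
#'   remaining entries strictly increasing.
#' @param intensities intensity at each dose (nonnegative; `NA` allowed).
#' @param pd,pdpd vehicle pulldown and consecutive-pulldown intensities.
#' @param unique_peptides,msms evidence counts.
#' @return An object of class `pulldown_series`.
#' @export
pulldown_series <- function(protein, doses, intensities, pd = NA_real_,
                            pdpd = NA_real_, unique_peptides = NA_integer_,
                            msms = NA_integer_) {
  stopifnot(length(doses) == length(intensities))
  if (doses[1L] != 0) .stopf("first dose must be the vehicle (0)")
  if (any(diff(doses[-1L]) <= 0)) .stopf("dose ladder must be strictly increasing after the vehicle")
  if (any(intensities[is.finite(intensities)] < 0)) .stopf("intensities must be nonnegative")
  structure(list(protein = protein, doses = as.numeric(doses),
                 intensities = as.numeric(intensities), pd = pd, pdpd = pdpd,
                 unique_peptides = unique_peptides, msms = msms),
            class = "pulldown_series")
}

#' Relative binding across the dose ladder
#'
#' Intensity ratio of every dose to the vehicle (DMSO) control:
#' `ratio(c) = intensity(c) / intensity(vehicle)`, with `ratio(0) = 1` by
#' construction. Scale-invariant: a constant factor on all intensities
#' cancels. A zero or missing vehicle intensity makes the series untestable.
#'
#' @param series a [pulldown_series].
#' @return Numeric vector of ratios (one per dose), or all-`NA` with
#'   attribute `untestable = TRUE` when the vehicle intensity is unusable.
#' @export
relative_binding <- function(series) {
  stopifnot(inherits(series, "pulldown_series"))
  v <- series$intensities[1L]
  if (!is.finite(v) || v <= 0) {
    r <- rep(NA_real_, length(series$doses))
    attr(r, "untestable") <- TRUE
    return(r)
  }
  r <- series$intensities / v
  r[1L] <- 1
  r
}

.logistic5 <- function(lx, bottom, lmid, slope, asym) {
  bottom + (1 - bottom) / (1 + 10^(slope * (lx - lmid)))^asym
}

#' Fit a five-parameter logistic competition-binding curve
#'
#' Fits the Richards (asymmetric) logistic with the top plateau fixed at 1 to
#' relative-binding ratios on the log10 dose axis:
#' `y(c) = bottom + (1 - bottom) / (1 + (c/x_mid)^slope)^asym`, with
#' `bottom` bounded to \[0, 1\]. The vehicle point is not fit directly; the
#' fixed top enforces `y -> 1` as the dose vanishes. Because the 5PL
#' inflection is not the half-response point, the EC50 is reported as the
#' concentration where the fitted curve crosses `(1 + bottom)/2`, which has
#' the closed form `EC50 = x_mid * (2^(1/asym) - 1)^(1/slope)` (so `asym = 1`
#' reduces to the 4PL with `EC50 = x_mid`).
#'
#' @param ratios relative-binding ratios (vehicle first, equal to 1).
#' @param doses dose ladder in molar (vehicle 0 first).
#' @param min_span minimum fitted span `1 - bottom` for a binder (default
#'   0.2); below it the series is flagged a non-binder and no EC50 is
#'   reported.
#' @return An object of class `competition_fit` with elements `parameters`
#'   (bottom, x_mid, slope, asym; top fixed at 1), `ec50`, `converged`,
#'   `binder`, `span`, `r2`, `data`.
#' @export
fit_competition_curve <- function(ratios, doses, min_span = 0.2) {
  stopifnot(length(ratios) == length(doses))
  keep <- is.finite(ratios) & is.finite(doses)
  if (sum(keep) < 5L)
    .stopf("at least 5 finite ratio points (including the vehicle) required")
  fitpts <- keep & doses > 0
  x <- doses[fitpts]; y <- ratios[fitpts]
  lx <- log10(x)
  no_fit <- list(parameters = c(bottom = NA_real_, x_mid = NA_real_,
                                slope = NA_real_, asym = NA_real_),
                 ec50 = NA_real_, converged = FALSE, binder = FALSE,
                 span = NA_real_, r2 = NA_real_,
                 data = data.frame(dose = doses, ratio = ratios))
  if (length(unique(x)) < 4L) return(structure(no_fit, class = "competition_fit"))
  b0 <- min(max(min(y), 0), 0.9)
  half <- (1 + b0) / 2
  lmid0 <- lx[which.min(abs(y - half))]
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ .logistic5(lx, bottom, lmid, slope, asym),
                      start = list(bottom = b0, lmid = lmid0, slope = 1, asym = 1),
                      lower = c(bottom = 0, lmid = min(lx) - 2, slope = 0.1, asym = 0.1),
                      upper = c(bottom = 1, lmid = max(lx) + 2, slope = 10, asym = 10),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(structure(no_fit, class = "competition_fit"))
  cf <- coef(fit)
  span <- 1 - cf[["bottom"]]
  ec50 <- 10^cf[["lmid"]] * (2^(1 / cf[["asym"]]) - 1)^(1 / cf[["slope"]])
  r2 <- 1 - sum(resid(fit)^2) / max(sum((y - mean(y))^2), .Machine$double.eps)
  binder <- span >= min_span
  out <- list(parameters = c(bottom = cf[["bottom"]], x_mid = 10^cf[["lmid"]],
                             slope = cf[["slope"]], asym = cf[["asym"]]),
              ec50 = if (binder) ec50 else NA_real_,
              converged = TRUE, binder = binder, span = span, r2 = r2,
              data = data.frame(dose = doses, ratio = ratios))
  structure(out, class = "competition_fit")
}

#' @export
print.competition_fit <- function(x, ...) {
  if (!x$converged) {
    cat("competition_fit: did not converge\n")
  } else if (!x$binder) {
    cat(sprintf("competition_fit: non-binder (span %.2f below minimum)\n", x$span))
  } else {
    p <- x$parameters
    cat(sprintf(
      "competition_fit: EC50 = %.3g M (bottom %.2f, x_mid %.3g, slope %.2f, asym %.2f, R2 %.3f)\n",
      x$ec50, p[["bottom"]], p[["x_mid"]], p[["slope"]], p[["asym"]], x$r2))
  }
  invisible(x)
}

#' @export
coef.competition_fit <- function(object, ...) object$parameters

#' @export
predict.competition_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$dose else
    if (is.list(newdata)) newdata$dose else newdata
  p <- object$parameters
  .logistic5(log10(conc), p[["bottom"]], log10(p[["x_mid"]]), p[["slope"]], p[["asym"]])
}

#' @export
plot.competition_fit <- function(x, ...) {
  d <- x$data
  pseudo <- min(d$dose[d$dose > 0]) / 100  # vehicle plotted 2 decades below
  px <- ifelse(d$dose == 0, pseudo, d$dose)
  plot(px, d$ratio, log = "x", xlab = "dose (M)", ylab = "relative binding",
       ylim = c(0, max(1.05, d$ratio, na.rm = TRUE)), ...)
  if (x$converged) {
    gx <- 10^seq(log10(pseudo), log10(max(d$dose)), length.out = 120)
    graphics::lines(gx, predict(x, gx))
  }
  invisible(x)
}

#' Bead-depletion correction factor from consecutive vehicle pulldowns
#'
#' `cf = pdpd / pd`: the intensity ratio of a protein between the second
#' (PDPD, re-pulldown of the vehicle flow-through with fresh beads) and first
#' (PD) vehicle pulldown. Strong bead-mediated depletion gives a small cf.
#' Values are clipped to `(eps, 1]` with a warning. Multiplying a fitted
#' EC50 by cf gives the apparent Kd.
#'
#' @param pd_intensity vehicle pulldown intensity (> 0).
#' @param pdpd_intensity consecutive-pulldown intensity; `NA` leaves cf
#'   undefined (EC50 is then reported alone).
#' @param eps lower clip bound (default 1e-3).
#' @return cf in `(eps, 1]`, or `NA` when undefined.
#' @export
depletion_correction_factor <- function(pd_intensity, pdpd_intensity, eps = 1e-3) {
  if (!is.finite(pd_intensity) || pd_intensity <= 0)
    .stopf("PD intensity must be positive")
  if (!is.finite(pdpd_intensity)) return(NA_real_)
  cf <- pdpd_intensity / pd_intensity
  if (cf > 1) { .warnf("cf = %.3g > 1 clipped to 1", cf); cf <- 1 }
  if (cf <= eps) { .warnf("cf = %.3g clipped to eps = %g", cf, eps); cf <- eps }
  cf
}

#' Apparent dissociation constant
#'
#' `Kd_app = EC50 * cf`: the fitted competition EC50 corrected for
#' bead-mediated target depletion. Since `cf <= 1`, `Kd_app <= EC50` always.
#'
#' @param ec50 fitted EC50 (molar).
#' @param cf depletion correction factor from
#'   [depletion_correction_factor()].
#' @return Kd_app in molar (`NA` if either input is undefined).
#' @export
apparent_kd <- function(ec50, cf) ec50 * cf

#' Fit a collection of pulldown series end to end
#'
#' For every [pulldown_series]: relative binding, 5PL fit, depletion
#' correction factor, apparent Kd, Spearman dose-trend, then target
#' annotation via [annotate_targets()].
#'
#' @param series list of [pulldown_series] objects.
#' @param criteria annotation thresholds, see [annotate_targets()].
#' @param min_span_fit minimum fitted span passed to
#'   [fit_competition_curve()].
#' @return A `binding_result` data frame, one row per protein.
#' @export
fit_pulldown <- function(series, criteria = target_criteria(), min_span_fit = 0.2) {
  rows <- lapply(series, function(s) {
    r <- relative_binding(s)
    if (isTRUE(attr(r, "untestable"))) {
      return(data.frame(protein = s$protein, ec50 = NA_real_, bottom = NA_real_,
                        x_mid = NA_real_, slope = NA_real_, asym = NA_real_,
                        span = NA_real_, r2 = NA_real_, converged = FALSE,
                        cf = NA_real_, kd_app = NA_real_, spearman = NA_real_,
                        unique_peptides = s$unique_peptides, msms = s$msms,
                        n_points = 0L, stringsAsFactors = FALSE))
    }
    fit <- fit_competition_curve(r, s$doses, min_span = min_span_fit)
    cf <- if (is.finite(s$pd) && s$pd > 0 && is.finite(s$pdpd))
      depletion_correction_factor(s$pd, s$pdpd) else NA_real_
    rho <- suppressWarnings(cor(r, s$doses, method = "spearman",
                                use = "complete.obs"))
    data.frame(protein = s$protein, ec50 = fit$ec50,
               bottom = fit$parameters[["bottom"]],
               x_mid = fit$parameters[["x_mid"]],
               slope = fit$parameters[["slope"]],
               asym = fit$parameters[["asym"]],
               span = fit$span, r2 = fit$r2, converged = fit$converged,
               cf = cf, kd_app = apparent_kd(fit$ec50, cf), spearman = rho,
               unique_peptides = s$unique_peptides, msms = s$msms,
               n_points = sum(is.finite(r)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- annotate_targets(out, criteria)
  class(out) <- c("binding_result", "data.frame")
  out
}

#' Target-annotation criteria
#'
#' @param min_span minimum fitted span `1 - bottom` (default 0.5).
#' @param min_r2 minimum curve-shape R-squared (default 0.8).
#' @param min_unique_peptides minimum unique-peptide evidence (default 2).
#' @param max_spearman maximum Spearman correlation of ratio vs dose
#'   (default -0.7; requires a monotone dose-dependent decrease).
#' @return A `target_criteria` list.
#' @export
target_criteria <- function(min_span = 0.5, min_r2 = 0.8,
                            min_unique_peptides = 2L, max_spearman = -0.7) {
  structure(list(min_span = min_span, min_r2 = min_r2,
                 min_unique_peptides = min_unique_peptides,
                 max_spearman = max_spearman), class = "target_criteria")
}

#' Annotate pulldown targets
#'
#' A protein is annotated as a target when its binding curve is a converged
#' sigmoid with a dose-dependent decrease of binding to the beads: fitted
#' span `1 - bottom >= min_span`, curve R-squared `>= min_r2`, Spearman of
#' ratio vs dose `<= max_spearman`, and at least `min_unique_peptides` unique
#' peptides of identification evidence.
#'
#' @param results a `binding_result`-shaped data frame (see
#'   [fit_pulldown()]).
#' @param criteria a [target_criteria()] list.
#' @return `results` with a logical `target` column; the criteria are
#'   attached as attribute `"criteria"`.
#' @export
annotate_targets <- function(results, criteria = target_criteria()) {
  stopifnot(inherits(criteria, "target_criteria"))
  ev <- results$unique_peptides
  ev_ok <- is.na(ev) | ev >= criteria$min_unique_peptides
  ev_ok[is.na(ev)] <- FALSE
  results$target <- results$converged &
    !is.na(results$span) & results$span >= criteria$min_span &
    !is.na(results$r2) & results$r2 >= criteria$min_r2 &
    !is.na(results$spearman) & results$spearman <= criteria$max_spearman &
    ev_ok
  attr(results, "criteria") <- criteria
  results
}
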