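#' Arginase activity from a colorimetric urea assay
#'
#' Converts plate-reader absorbances into arginase activity (units per
#' liter):
#' `activity = (absorbance - blank) / (urea_standard - h2o_control) *
#'  (1 mM * reaction_volume * 1e3) / (incubation_time * sample_volume)`.
#' One unit converts 1.0 umol of L-arginine to ornithine and urea per minute.
#' The result is linear in `absorbance - blank` and inversely proportional to
#' incubation time and sample volume. Volumes are in microliters, time in
#' minutes; any kit constant can be substituted by rescaling the inputs.
#'
#' @param absorbance sample absorbance (OD; may be a vector).
#' @param blank reagent blank absorbance (OD).
#' @param urea_standard,h2o_control calibration absorbances (OD; must
#'   differ).
#' @param reaction_volume reaction volume in uL.
#' @param incubation_time incubation time in minutes.
#' @param sample_volume sample volume in uL.
#' @return Arginase activity in U/L (same length as `absorbance`).
#' @export
#' @examples
#' arginase_activity(0.8, 0.3, 0.9, 0.4, reaction_volume = 100,
#'                   incubation_time = 120, sample_volume = 40)
arginase_activity <- function(absorbance, blank, urea_standard, h2o_control,
                              reaction_volume, incubation_time, sample_volume) {
  .check_num(reaction_volume, "reaction_volume", min = .Machine$double.xmin)
  .check_num(incubation_time, "incubation_time", min = .Machine$double.xmin)
  .check_num(sample_volume, "sample_volume", min = .Machine$double.xmin)
  denom <- urea_standard - h2o_control
  if (!is.finite(denom) || denom == 0)
    .stopf("urea standard and H2O control absorbances must differ")
  (absorbance - blank) / denom *
    (1 * reaction_volume * 1e3) / (incubation_time * sample_volume)
}

#' Summary statistics for per-cell ROS imaging intensities
#'
#' Respecting the independent treatment replicate as the experimental unit,
#' per-cell intensities are first averaged within each condition x replicate,
#' then the replicate means are compared across conditions by one-way ANOVA
#' followed by Tukey's HSD post hoc test.
#'
#' @param intensity per-cell mean signal intensities.
#' @param condition condition label per cell.
#' @param replicate replicate id per cell.
#' @param min_cells minimum cells expected per condition x replicate
#'   (default 100); a shortfall triggers a warning, not an error.
#' @return An object of class `ros_summary`: list with `means` (per-condition
#'   mean of replicate means), `replicate_means`, `group_sizes`, `anova_f`,
#'   `anova_p`, `tukey` (pairwise adjusted p-values).
#' @export
ros_summary <- function(intensity, condition, replicate, min_cells = 100L) {
  stopifnot(length(intensity) == length(condition),
            length(intensity) == length(replicate))
  condition <- as.factor(condition)
  if (nlevels(condition) < 2L) .stopf("at least two conditions required")
  cell_counts <- table(condition, replicate)
  if (any(cell_counts > 0 & cell_counts < min_cells))
    .warnf("some condition x replicate groups have fewer than %d cells", min_cells)
  agg <- stats::aggregate(intensity,
                          by = list(condition = condition, replicate = replicate),
                          FUN = mean)
  names(agg)[3L] <- "mean_intensity"
  fit <- aov(mean_intensity ~ condition, data = agg)
  an <- summary(fit)[[1L]]
  tk <- TukeyHSD(fit)$condition
  structure(list(
    means = tapply(agg$mean_intensity, agg$condition, mean),
    replicate_means = agg,
    group_sizes = table(agg$condition),
    anova_f = an[["F value"]][1L],
    anova_p = an[["Pr(>F)"]][1L],
    tukey = tk), class = "ros_summary")
}

#' @export
print.ros_summary <- function(x, ...) {
  cat(sprintf("ros_summary: one-way ANOVA F = %.3g, p = %.3g\n", x$anova_f, x$anova_p))
  cat("condition means (of replicate means):\n")
  print(round(x$means, 3))
  cat("Tukey HSD adjusted p-values:\n")
  print(round(x$tukey[, "p adj", drop = FALSE], 4))
  invisible(x)
}
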