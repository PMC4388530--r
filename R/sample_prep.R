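# Dilution planning for sample preparation.
#
# Samples are diluted with demineralized water to a target optical
# density before imaging: too dense a sample crowds the field of view
# and breaks the tracking (see the too_crowded QC flag). OD is assumed
# linear in concentration over the working range, so the dilution
# factor is simply od_measured / od_target; the executed dilution is
# verified gravimetrically.

#' Plan a dilution to the target optical density
#'
#' @param od_measured measured OD600 of the sample (> 0).
#' @param sample_mass sample mass, g (> 0).
#' @param od_target target OD600; default 1.15, the density found
#'   optimal for movement tracking in the flow cell.
#' @param density assumed density of sample and diluent, g/ml
#'   (default 1.000).
#' @return A `dilution_plan`: `od_measured`, `od_target`,
#'   `dilution_factor` (clipped to >= 1), `sample_mass`,
#'   `water_mass_to_add` (g), `already_dilute` (TRUE when the sample
#'   was at or below target and no water is added).
#' @export
plan_dilution <- function(od_measured, sample_mass, od_target = 1.15,
                          density = 1.0) {
  if (od_measured <= 0 || sample_mass <= 0 || od_target <= 0 ||
      density <= 0)
    stop("od_measured, sample_mass, od_target and density must be positive")
  factor <- od_measured / od_target
  already_dilute <- factor < 1
  if (already_dilute) {
    factor <- 1
    warning("sample is already below the target OD; cannot concentrate")
  }
  structure(list(od_measured = od_measured, od_target = od_target,
                 dilution_factor = factor, sample_mass = sample_mass,
                 water_mass_to_add = sample_mass * (factor - 1),
                 already_dilute = already_dilute),
            class = "dilution_plan")
}

#' @export
print.dilution_plan <- function(x, ...) {
  cat(sprintf(
    "<dilution_plan> OD %.3f -> %.3f: factor %.3f, add %.2f g water to %.2f g sample\n",
    x$od_measured, x$od_target, x$dilution_factor,
    x$water_mass_to_add, x$sample_mass))
  invisible(x)
}

#' Verify an executed dilution gravimetrically
#'
#' Compares the measured total mass after water addition with the
#' expected `sample_mass * dilution_factor`.
#'
#' @param plan a [plan_dilution()] result.
#' @param measured_total_mass total mass on the balance, g.
#' @param tolerance_pct symmetric relative tolerance, percent (> 0).
#'   The default 2% reflects routine balance and pipetting accuracy.
#' @return `TRUE` (pass) or `FALSE` (fail).
#' @export
verify_dilution <- function(plan, measured_total_mass,
                            tolerance_pct = 2) {
  stopifnot(inherits(plan, "dilution_plan"), tolerance_pct > 0)
  expected <- plan$sample_mass * plan$dilution_factor
  abs(measured_total_mass - expected) <= tolerance_pct / 100 * expected
}
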