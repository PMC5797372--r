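#' APOE genotype labels
#'
#' @return Character vector of the three genotype labels.
#' @export
apoe_genotypes <- function() c("APOE4-/-", "APOE4+/-", "APOE4+/+")

# placebo deposition, units per 13 weeks, identical on both axes;
# 1 unit/13 weeks for the heterozygote defines the model's amyloid unit
.apoe_base_rates <- c("APOE4-/-" = 0.5, "APOE4+/-" = 1.0, "APOE4+/+" = 1.5)

.check_genotype <- function(genotype) {
  if (!is.character(genotype) || length(genotype) != 1L ||
      !genotype %in% apoe_genotypes())
    stop("`genotype` must be one of ", paste(apoe_genotypes(), collapse = ", "),
         call. = FALSE)
  genotype
}

#' Therapeutic intervention pharmacodynamics
#'
#' An intervention is characterised by the fraction of Aβ40 and Aβ42
#' deposition it suppresses, taken from the clinical target-engagement
#' (biomarker) changes reported for each drug class.
#'
#' @param name Intervention name.
#' @param reduction_x Fractional reduction of Aβ40 deposition, in `[0, 1]`.
#' @param reduction_y Fractional reduction of Aβ42 deposition, in `[0, 1]`.
#' @param dose_label Free-text dose label (e.g. `"low"`, `"high"`).
#' @return An object of class `intervention_pd`.
#' @export
#' @examples
#' intervention("GSI", 0.4, 0.2, "low")
intervention <- function(name, reduction_x, reduction_y, dose_label = "") {
  for (nm in c("reduction_x", "reduction_y")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 || v > 1)
      stop("`", nm, "` must be a single number in [0, 1]", call. = FALSE)
  }
  structure(list(name = as.character(name), reduction_x = reduction_x,
                 reduction_y = reduction_y, dose_label = as.character(dose_label)),
            class = "intervention_pd")
}

#' @export
print.intervention_pd <- function(x, ...) {
  cat(sprintf("Intervention %s (%s dose): Ab40 reduction %.0f%%, Ab42 reduction %.0f%%\n",
              x$name, ifelse(nzchar(x$dose_label), x$dose_label, "unspecified"),
              100 * x$reduction_x, 100 * x$reduction_y))
  invisible(x)
}

#' Library of amyloid-modulating interventions
#'
#' The reported pharmacodynamic reductions per drug class: BACE inhibition
#' (verubecestat) reduces Aβ40 by 80-90% and Aβ42 by 60-80%; gamma-secretase
#' inhibition (semagacestat) by 30-50% and 15-30%; solanezumab by 5-10% and
#' 30-50%. Low/high doses take the range endpoints, except the low GSI dose,
#' whose published worked example (an increase of 0.6 units along the Aβ40
#' axis and 0.80 along the Aβ42 axis per 13 weeks) corresponds to 40% and
#' 20% reductions.
#'
#' @return Named list of [intervention()] objects
#'   (`bace_low`, `bace_high`, `gsi_low`, `gsi_high`, `sola_low`,
#'   `sola_high`).
#' @export
intervention_library <- function() {
  list(
    bace_low  = intervention("BACE-I", 0.80, 0.60, "low"),
    bace_high = intervention("BACE-I", 0.90, 0.80, "high"),
    gsi_low   = intervention("GSI", 0.40, 0.20, "low"),
    gsi_high  = intervention("GSI", 0.50, 0.30, "high"),
    sola_low  = intervention("solanezumab", 0.05, 0.30, "low"),
    sola_high = intervention("solanezumab", 0.10, 0.50, "high")
  )
}

#' Amyloid deposition schedule for a genotype under an intervention
#'
#' Placebo deposition is 0.5, 1.0 and 1.5 units per 13 weeks for
#' APOE4-/-, APOE4+/- and APOE4+/+ respectively, identical on both
#' isoform axes. An active intervention proportionally lowers the accrual
#' on each axis by its fractional biomarker reduction; baseline load is
#' never removed retroactively (steady-state pharmacology from week 0).
#'
#' @param genotype One of [apoe_genotypes()].
#' @param intervention An [intervention()] object, or `NULL` for placebo.
#' @return An object of class `deposition_schedule` with `rate_x`,
#'   `rate_y` (units per 13 weeks) and `genotype`.
#' @export
#' @examples
#' deposition_rate("APOE4+/-", intervention_library()$gsi_low)  # 0.6, 0.8
deposition_rate <- function(genotype = "APOE4+/-", intervention = NULL) {
  .check_genotype(genotype)
  base <- .apoe_base_rates[[genotype]]
  if (is.null(intervention)) {
    rx <- ry <- base
  } else {
    stopifnot(inherits(intervention, "intervention_pd"))
    rx <- base * (1 - intervention$reduction_x)
    ry <- base * (1 - intervention$reduction_y)
  }
  structure(list(rate_x = rx, rate_y = ry, genotype = genotype),
            class = "deposition_schedule")
}

#' @export
print.deposition_schedule <- function(x, ...) {
  cat(sprintf("Deposition schedule (%s): %.3g / %.3g units per 13 weeks (Ab40 / Ab42)\n",
              x$genotype, x$rate_x, x$rate_y))
  invisible(x)
}

#' Linear amyloid load trajectory
#'
#' Loads grow linearly: `load(t) = start + rate * t / 13` per axis,
#' clamped at 16 units (the grid ceiling) with a warning when clamping
#' occurs.
#'
#' @param start Starting [abeta_load()].
#' @param schedule A [deposition_rate()] schedule.
#' @param weeks Non-negative, ascending vector of trial weeks.
#' @return A data.frame with columns `week`, `x`, `y`.
#' @export
load_trajectory <- function(start, schedule, weeks) {
  start <- .load_xy(start)
  stopifnot(inherits(schedule, "deposition_schedule"))
  if (length(start$x) != 1L) stop("`start` must be a single load", call. = FALSE)
  if (any(weeks < 0) || is.unsorted(weeks))
    stop("`weeks` must be non-negative and ascending", call. = FALSE)
  x <- start$x + schedule$rate_x * weeks / 13
  y <- start$y + schedule$rate_y * weeks / 13
  if (any(x > 16) || any(y > 16))
    warning("load trajectory clamped at the 16-unit grid ceiling")
  data.frame(week = weeks, x = pmin(x, 16), y = pmin(y, 16))
}

#' Mass-conserving three-point quadrature weights
#'
#' Treatment produces fractional effective loads; matrix cells exist only
#' at integer loads. Effects are therefore evaluated as a weighted average
#' over three consecutive integer cells, with the weights chosen so that
#' (i) they sum to 1, (ii) the centre weight is 1/3, and (iii) the
#' weighted mean of the support equals the effective load (the mass
#' average of the load corresponds to the actual load). With support
#' `{m-1, m, m+1}` and effective load `L` the closed form is
#' `w_low = 1/3 + (m - L)/2`, `w_mid = 1/3`, `w_high = 1/3 - (m - L)/2`.
#' Negative weights are legal linear extrapolation (for the low-dose
#' BACE-I worked case, load 4.2 against the placebo destination window
#' `{4, 5, 6}`, they are 0.7333, 0.3333 and -0.0667).
#'
#' The support is anchored at `anchor` (the window centre). For treated
#' arms the window is anchored at the placebo (untreated) destination
#' cell, which is what reproduces the published weights; by default the
#' anchor is the nearest integer, shifted inward at the grid edges.
#'
#' @param effective_load Effective load in units, in `[0, 16]`.
#' @param anchor Integer window centre in `[1, 15]`; default
#'   `round(effective_load)` shifted into `[1, 15]`.
#' @return An object of class `quadrature_weights`: list with `support`
#'   (three consecutive integers) and `weights` (three reals summing to 1).
#' @export
#' @examples
#' quadrature_weights(4.2, anchor = 5)$weights  # 0.7333 0.3333 -0.0667
quadrature_weights <- function(effective_load, anchor = NULL) {
  if (!is.numeric(effective_load) || length(effective_load) != 1L ||
      !is.finite(effective_load) || effective_load < 0 || effective_load > 16)
    stop("`effective_load` must be a single number in [0, 16]", call. = FALSE)
  if (is.null(anchor)) anchor <- round(effective_load)
  if (anchor != round(anchor)) stop("`anchor` must be an integer", call. = FALSE)
  anchor <- min(max(anchor, 1), 15)
  d <- anchor - effective_load
  structure(list(support = (anchor - 1):(anchor + 1),
                 weights = c(1 / 3 + d / 2, 1 / 3, 1 / 3 - d / 2)),
            class = "quadrature_weights")
}

#' @export
print.quadrature_weights <- function(x, ...) {
  cat(sprintf("Quadrature weights on {%s}: %s (sum %.3g)\n",
              paste(x$support, collapse = ", "),
              paste(sprintf("%.4f", x$weights), collapse = ", "),
              sum(x$weights)))
  invisible(x)
}

#' Quadrature-weighted 3 x 3 matrix average at a (fractional) load
#'
#' Applies the tensor product of the per-axis [quadrature_weights()] to
#' the 3 x 3 block of cells around the load: for a patient at integer load
#' (4, 4) this is the plain mean of the block `3 <= x <= 5`,
#' `3 <= y <= 5`; for fractional loads it is the mass-conserving weighted
#' average, which reproduces any affine function of `(x, y)` exactly.
#'
#' @param matrix An `effect_matrix`, or a function `f(x, y)` returning a
#'   cell value (used by the oracle tests).
#' @param load An [abeta_load()] with the effective (possibly fractional)
#'   load.
#' @param anchor_x,anchor_y Integer window centres per axis (see
#'   [quadrature_weights()]); default nearest integers.
#' @return For an `effect_matrix`, a list with `g_ratio` and `a7_factor`;
#'   for a function, the scalar weighted average.
#' @export
sample_matrix_average <- function(matrix, load, anchor_x = NULL, anchor_y = NULL) {
  load <- .load_xy(load)
  qx <- quadrature_weights(load$x, anchor_x)
  qy <- quadrature_weights(load$y, anchor_y)
  cells <- expand.grid(x = qx$support, y = qy$support, KEEP.OUT.ATTRS = FALSE)
  w <- as.vector(outer(qx$weights, qy$weights))
  if (is.function(matrix)) {
    return(sum(w * matrix(cells$x, cells$y)))
  }
  vals <- effect_matrix_cells(matrix, cells$x, cells$y)
  list(g_ratio = sum(w * vals$g_ratio), a7_factor = sum(w * vals$a7_factor))
}
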