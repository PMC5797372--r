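#' Amyloid-beta coupling parameters
#'
#' Constants of the isoform-specific coupling between low-order
#' amyloid-beta aggregate load (monomer, dimer, trimer) and synaptic
#' function. Aβ40 load `x` has a biphasic effect on the maximal NMDA
#' conductance of excitatory-excitatory synapses: a linear benefit up to a
#' peak at `x = x0` of relative magnitude `delta`, then a linear decline
#' with slope `alpha`. Aβ42 load `y` decreases NMDA conductance
#' monotonically with slope `alpha_star`. Both isoforms jointly depress
#' alpha7 nicotinic receptor activation with a single coupling factor
#' `beta` applied to `x + y`.
#'
#' @param x0 Aβ40 load (units, integer grid position in `[0, 16]`) at which
#'   the NMDA benefit is maximal.
#' @param delta Maximal relative NMDA conductance benefit (dimensionless,
#'   >= 0).
#' @param alpha Post-peak Aβ40 decline slope (per unit, >= 0).
#' @param alpha_star Aβ42 decline slope (per unit, >= 0).
#' @param beta alpha7 coupling factor (per unit of `x + y`, >= 0).
#'   `beta * 32` may exceed 1; activation is floored at 0 downstream.
#' @return An object of class `coupling_params`.
#' @seealso [coupling_presets()] for the parameter sets used in the
#'   clinical-constraint analyses.
#' @export
#' @examples
#' coupling_params(x0 = 2, delta = 0.025, alpha = 0.002,
#'                 alpha_star = 0.002, beta = 0.03)
coupling_params <- function(x0 = 2, delta = 0.025, alpha = 0.002,
                            alpha_star = 0.002, beta = 0.03) {
  for (nm in c("x0", "delta", "alpha", "alpha_star", "beta")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("`", nm, "` must be a single non-negative finite number", call. = FALSE)
  }
  if (x0 > 16) stop("`x0` must lie in [0, 16]", call. = FALSE)
  structure(list(x0 = x0, delta = delta, alpha = alpha,
                 alpha_star = alpha_star, beta = beta),
            class = "coupling_params")
}

#' @export
print.coupling_params <- function(x, ...) {
  cat("Amyloid-beta coupling parameters\n")
  cat(sprintf("  x0 = %g units, delta = %g, alpha = %g, alpha* = %g, beta = %g\n",
              x$x0, x$delta, x$alpha, x$alpha_star, x$beta))
  invisible(x)
}

#' Named coupling-parameter presets
#'
#' Two parameter sets are used throughout: `"final"`, the set retained for
#' the intervention simulations after the sensitivity analysis
#' (x0 = 2, delta = 0.025, alpha = alpha* = 0.002, beta = 0.03), and
#' `"mci_calibration"`, the set under which the MCI region averages
#' (7.4 ADAS-Cog points for Aβ-negative, 10.4 for Aβ-positive subjects at a
#' cutoff of 3 units) were derived
#' (delta = 0.015, alpha = 0.0015, alpha* = 0.00035, beta = 0.025).
#'
#' @param name One of `"final"`, `"mci_calibration"`.
#' @return A [coupling_params()] object.
#' @export
coupling_presets <- function(name = c("final", "mci_calibration")) {
  name <- match.arg(name)
  switch(name,
    final = coupling_params(x0 = 2, delta = 0.025, alpha = 0.002,
                            alpha_star = 0.002, beta = 0.03),
    mci_calibration = coupling_params(x0 = 2, delta = 0.015, alpha = 0.0015,
                                      alpha_star = 0.00035, beta = 0.025))
}

.check_load <- function(x, y) {
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("loads must be finite", call. = FALSE)
  if (any(x < 0 | x > 16) || any(y < 0 | y > 16))
    stop("Abeta load out of bounds: x and y must lie in [0, 16]", call. = FALSE)
}

#' Amyloid-beta load pair
#'
#' A pair of Aβ40 (`x`) and Aβ42 (`y`) low-order aggregate loads in model
#' units on the `[0, 16]` grid. Non-integer values are legal (the trial
#' engine produces fractional loads under treatment); only integer values
#' index the effect matrix.
#'
#' @param x Aβ40 load (units).
#' @param y Aβ42 load (units).
#' @return An object of class `abeta_load` (a named list with `x`, `y`).
#' @export
abeta_load <- function(x, y) {
  .check_load(x, y)
  if (length(x) != length(y))
    stop("`x` and `y` must have equal length", call. = FALSE)
  structure(list(x = x, y = y), class = "abeta_load")
}

#' @export
print.abeta_load <- function(x, ...) {
  cat(sprintf("Abeta load: x (Ab40) = %s, y (Ab42) = %s units\n",
              paste(signif(x$x, 4), collapse = ", "),
              paste(signif(x$y, 4), collapse = ", ")))
  invisible(x)
}

.load_xy <- function(load) {
  if (inherits(load, "abeta_load")) return(load)
  if (is.numeric(load) && length(load) == 2L) return(abeta_load(load[1], load[2]))
  stop("`load` must be an `abeta_load` or a numeric length-2 vector", call. = FALSE)
}

#' Relative NMDA conductance under amyloid load
#'
#' Evaluates the biphasic glutamatergic coupling: the relative
#' excitatory-excitatory NMDA conductance g/g0 grows linearly with Aβ40
#' load up to `1 + delta` at `x = x0`, declines with slope `alpha` beyond
#' the peak, and decreases linearly in Aβ42 load with slope `alpha_star`
#' throughout. When `x0 = 0` the peak sits at the origin and only the
#' post-peak branch is used (no division by zero). The result is floored
#' at `floor` (default 0; conductances cannot be negative) and has no
#' ceiling.
#'
#' @param load An [abeta_load()] (or numeric `c(x, y)`); vectorised over
#'   loads of equal length.
#' @param params A [coupling_params()] object.
#' @param floor Lower bound applied to the result (default 0).
#' @return Relative conductance g/g0 (dimensionless, >= `floor`).
#' @export
#' @examples
#' p <- coupling_presets("final")
#' glu_conductance_factor(abeta_load(4, 4), p)  # 1.013
glu_conductance_factor <- function(load, params, floor = 0) {
  load <- .load_xy(load)
  stopifnot(inherits(params, "coupling_params"))
  x <- load$x; y <- load$y
  g <- ifelse(params$x0 > 0 & x <= params$x0,
              1 + params$delta * (x / max(params$x0, .Machine$double.eps)),
              1 + params$delta + (params$x0 - x) * params$alpha)
  g <- g - y * params$alpha_star
  pmax(g, floor)
}

#' Relative alpha7 nicotinic activation under amyloid load
#'
#' Both amyloid isoforms act identically on the alpha7 nicotinic receptor:
#' relative activation (baseline normalised to 1) is
#' `max(0, 1 - beta * (x + y))`.
#'
#' @inheritParams glu_conductance_factor
#' @return Relative alpha7 activation, a fraction in `[0, 1]`.
#' @export
#' @examples
#' a7_activation_factor(abeta_load(16, 16), coupling_params(beta = 0.025))  # 0.2
a7_activation_factor <- function(load, params) {
  load <- .load_xy(load)
  stopifnot(inherits(params, "coupling_params"))
  pmax(0, 1 - params$beta * (load$x + load$y))
}

#' Build the 17 x 17 amyloid effect matrix
#'
#' Evaluates the two point couplings on every integer `(x, y)` grid cell,
#' `x, y = 0, ..., 16` (289 cells).
#'
#' @param params A [coupling_params()] object.
#' @return An object of class `effect_matrix`: a list with `grid` (a
#'   data.frame with columns `x`, `y`, `g_ratio`, `a7_factor`) and
#'   `params`.
#' @export
build_effect_matrix <- function(params) {
  stopifnot(inherits(params, "coupling_params"))
  grid <- expand.grid(x = 0:16, y = 0:16, KEEP.OUT.ATTRS = FALSE)
  grid$g_ratio <- glu_conductance_factor(abeta_load(grid$x, grid$y), params)
  grid$a7_factor <- a7_activation_factor(abeta_load(grid$x, grid$y), params)
  structure(list(grid = grid, params = params), class = "effect_matrix")
}

#' @export
print.effect_matrix <- function(x, ...) {
  cat("Amyloid effect matrix: 17 x 17 integer (Ab40, Ab42) grid\n")
  cat(sprintf("  g_ratio in [%.4f, %.4f]; a7_factor in [%.4f, %.4f]\n",
              min(x$grid$g_ratio), max(x$grid$g_ratio),
              min(x$grid$a7_factor), max(x$grid$a7_factor)))
  print(x$params)
  invisible(x)
}

#' @export
as.data.frame.effect_matrix <- function(x, ...) x$grid

#' Look up effect-matrix cells
#'
#' @param matrix An `effect_matrix`.
#' @param x,y Integer grid coordinates (vectorised).
#' @return A data.frame with `g_ratio` and `a7_factor` for each cell.
#' @keywords internal
effect_matrix_cells <- function(matrix, x, y) {
  stopifnot(inherits(matrix, "effect_matrix"))
  idx <- match(paste(x, y), paste(matrix$grid$x, matrix$grid$y))
  if (anyNA(idx)) stop("cell outside the integer grid", call. = FALSE)
  matrix$grid[idx, c("g_ratio", "a7_factor")]
}

#' Partition the load grid into amyloid-negative and -positive regions
#'
#' The clinical partition fixes a cutoff (default 3 units): Aβ-negative
#' subjects have `x < cutoff` and `y < cutoff`; Aβ-positive subjects have
#' `x >= cutoff` and `y >= cutoff` (mode `"both-axes"`, the Results-text
#' convention; mixed cells are excluded). Mode `"complement"` instead takes
#' Aβ-positive to be every cell outside the negative box, as the
#' everything-outside-the-gray-area reading of the pipeline figure.
#'
#' @param cutoff Integer cutoff in units, `1 <= cutoff <= 16`.
#' @param mode `"both-axes"` or `"complement"`.
#' @return An object of class `region_partition` with `neg_cells` and
#'   `pos_cells` data.frames (columns `x`, `y`), plus `cutoff`, `mode`.
#' @export
#' @examples
#' p <- region_partition(3)
#' nrow(p$neg_cells)  # 9
#' nrow(p$pos_cells)  # 196
region_partition <- function(cutoff = 3, mode = c("both-axes", "complement")) {
  mode <- match.arg(mode)
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff != round(cutoff) ||
      cutoff < 1 || cutoff > 16)
    stop("`cutoff` must be a single integer in [1, 16]", call. = FALSE)
  grid <- expand.grid(x = 0:16, y = 0:16, KEEP.OUT.ATTRS = FALSE)
  neg <- grid[grid$x < cutoff & grid$y < cutoff, , drop = FALSE]
  pos <- if (mode == "both-axes") {
    grid[grid$x >= cutoff & grid$y >= cutoff, , drop = FALSE]
  } else {
    grid[!(grid$x < cutoff & grid$y < cutoff), , drop = FALSE]
  }
  rownames(neg) <- rownames(pos) <- NULL
  structure(list(cutoff = cutoff, mode = mode,
                 neg_cells = neg, pos_cells = pos),
            class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat(sprintf("Region partition at cutoff %d (%s): %d Abeta- cells, %d Abeta+ cells\n",
              x$cutoff, x$mode, nrow(x$neg_cells), nrow(x$pos_cells)))
  invisible(x)
}

#' Export the effect matrix as a delimited table
#'
#' Writes columns `x`, `y`, `g_ratio`, `a7_factor` as comma-separated
#' values with a commented header line naming the units.
#'
#' @param matrix An `effect_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_effect_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "effect_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# amyloid effect matrix: x = Ab40 load (units),",
                   "y = Ab42 load (units), g_ratio = relative NMDA conductance,",
                   "a7_factor = relative alpha7 activation"), con)
  utils::write.csv(matrix$grid, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
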