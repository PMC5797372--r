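#' Evaluate the three clinical constraint conditions for a parameter set
#'
#' The three clinical datasets the coupling parameters must jointly
#' reproduce:
#' \describe{
#'   \item{c1}{MCI region averages — some integer cutoff below 4 (searched
#'     over 1, 2, 3) yields an Aβ-negative mean ADAS-Cog within 8.5 ± 1
#'     and an Aβ-positive mean within 10.7 ± 1.}
#'   \item{c2}{Scopolamine sensitivity — the Aβ-positive MCI population
#'     has the steeper (more negative) dose-response slope at cutoff 3.}
#'   \item{c3}{APOE trajectories — the three genotype slopes differ by at
#'     most 10% (relative spread) while the APOE4+/+ baseline is at least
#'     1.5 points worse than APOE4-/- at week 0.}
#' }
#'
#' @param coupling A [coupling_params()] object.
#' @param params A [surrogate_params()] object.
#' @param receptor A [receptor_params()] object.
#' @param cutoffs Integer cutoffs searched for condition 1.
#' @return A list of class `condition_report`: `coupling`, booleans `c1`,
#'   `c2`, `c3`, and `metrics` (region averages per cutoff with the best
#'   cutoff, scopolamine slopes, APOE slope spread and week-0 gap).
#' @export
#' @examples
#' \donttest{evaluate_conditions(coupling_presets("final"))}
evaluate_conditions <- function(coupling,
                                params = surrogate_params(),
                                receptor = receptor_params(),
                                cutoffs = 1:3) {
  stopifnot(inherits(coupling, "coupling_params"))
  regions <- do.call(rbind, lapply(cutoffs, function(ct) {
    m <- mci_region_averages(coupling, ct, params, receptor)
    data.frame(cutoff = ct, neg = m[["neg"]], pos = m[["pos"]],
               ok = abs(m[["neg"]] - 8.5) <= 1 & abs(m[["pos"]] - 10.7) <= 1)
  }))
  c1 <- any(regions$ok)
  best <- if (c1) regions$cutoff[regions$ok][1] else NA_integer_
  dr <- scopolamine_dose_response(coupling = coupling, params = params,
                                  receptor = receptor)
  c2 <- abs(dr$slopes[["pos"]]) > abs(dr$slopes[["neg"]])
  ap <- apoe_slope_analysis(coupling = coupling, params = params,
                            receptor = receptor)
  c3 <- ap$max_rel_spread <= 0.10 && ap$week0_gap >= 1.5
  structure(list(coupling = coupling, c1 = c1, c2 = c2, c3 = c3,
                 metrics = list(regions = regions, best_cutoff = best,
                                scop_slopes = dr$slopes,
                                apoe_spread = ap$max_rel_spread,
                                apoe_week0_gap = ap$week0_gap)),
            class = "condition_report")
}

#' @export
print.condition_report <- function(x, ...) {
  cat(sprintf("Conditions at delta=%g, alpha=%g, alpha*=%g, beta=%g: c1 %s, c2 %s, c3 %s\n",
              x$coupling$delta, x$coupling$alpha, x$coupling$alpha_star,
              x$coupling$beta, x$c1, x$c2, x$c3))
  invisible(x)
}

#' Default sensitivity-scan grid
#'
#' Value lists spanning every coupling value quoted in the constraint
#' analysis: delta 0-0.03 (7 values), alpha and alpha* 0.0005-0.0025
#' (5 values each), beta 0.005-0.035 (4 values).
#'
#' @return Named list of numeric vectors `delta`, `alpha`, `alpha_star`,
#'   `beta`.
#' @export
default_sensitivity_grid <- function() {
  list(delta = c(0, 0.005, 0.01, 0.015, 0.02, 0.025, 0.03),
       alpha = c(0.0005, 0.001, 0.0015, 0.002, 0.0025),
       alpha_star = c(0.0005, 0.001, 0.0015, 0.002, 0.0025),
       beta = c(0.005, 0.015, 0.025, 0.035))
}

#' Parameter-grid sensitivity scan over the three conditions
#'
#' Exhaustive Cartesian scan of the coupling-parameter grid at fixed
#' `x0`, evaluating [evaluate_conditions()] in every cell. A pure map:
#' each cell's report is independent of the scan order.
#'
#' @param grid Named list of value vectors (`delta`, `alpha`,
#'   `alpha_star`, `beta`), e.g. [default_sensitivity_grid()].
#' @param x0 Fixed Aβ40 peak position (default 2).
#' @param params A [surrogate_params()] object.
#' @param receptor A [receptor_params()] object.
#' @return A data.frame of class `sensitivity_scan` with one row per grid
#'   cell: the four parameters, `c1`, `c2`, `c3`, `all3`, and the key
#'   metrics (region averages at the best cutoff, scopolamine slopes,
#'   APOE spread and gap).
#' @export
grid_scan <- function(grid = default_sensitivity_grid(), x0 = 2,
                      params = surrogate_params(),
                      receptor = receptor_params()) {
  need <- c("delta", "alpha", "alpha_star", "beta")
  if (!all(need %in% names(grid)) || any(lengths(grid[need]) == 0))
    stop("`grid` must provide non-empty ", paste(need, collapse = ", "),
         call. = FALSE)
  cells <- expand.grid(delta = grid$delta, alpha = grid$alpha,
                       alpha_star = grid$alpha_star, beta = grid$beta,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cp <- coupling_params(x0 = x0, delta = cells$delta[i],
                          alpha = cells$alpha[i],
                          alpha_star = cells$alpha_star[i],
                          beta = cells$beta[i])
    rep_ <- evaluate_conditions(cp, params, receptor)
    reg <- rep_$metrics$regions
    best <- rep_$metrics$best_cutoff
    use <- if (is.na(best)) reg[reg$cutoff == 3, ] else reg[reg$cutoff == best, ]
    data.frame(delta = cp$delta, alpha = cp$alpha, alpha_star = cp$alpha_star,
               beta = cp$beta, c1 = rep_$c1, c2 = rep_$c2, c3 = rep_$c3,
               all3 = rep_$c1 && rep_$c2 && rep_$c3,
               best_cutoff = best, adas_neg = use$neg, adas_pos = use$pos,
               scop_slope_neg = rep_$metrics$scop_slopes[["neg"]],
               scop_slope_pos = rep_$metrics$scop_slopes[["pos"]],
               apoe_spread = rep_$metrics$apoe_spread,
               apoe_week0_gap = rep_$metrics$apoe_week0_gap)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sensitivity_scan", "data.frame")
  out
}

#' Summarise the all-three region of a sensitivity scan
#'
#' @param scan A [grid_scan()] result.
#' @return A list: number of cells meeting all three conditions, the
#'   minimum `delta` and minimum `alpha + alpha_star` among them (the
#'   frontier), and the passing subset.
#' @export
scan_frontier <- function(scan) {
  stopifnot(inherits(scan, "sensitivity_scan"))
  hit <- scan[scan$all3, , drop = FALSE]
  list(n_all3 = nrow(hit),
       min_delta = if (nrow(hit)) min(hit$delta) else NA_real_,
       min_alpha_sum = if (nrow(hit)) min(hit$alpha + hit$alpha_star) else NA_real_,
       cells = hit)
}
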