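#' Scopolamine dose-response in an MCI population
#'
#' Evaluates the 2-back working-memory accuracy of MCI virtual patients
#' under increasing scopolamine dose, separately for the Aβ-negative and
#' Aβ-positive regions of the load grid. At each dose the cholinergic
#' chain (M2-autoreceptor disinhibition of ACh release, competitive M1
#' blockade, ACh-driven alpha7 and alpha4beta2 drive) is evaluated and the
#' accuracy is averaged over the region's integer cells; a linear slope
#' (% correct per nM) is then fitted to each region's curve by ordinary
#' least squares.
#'
#' With the default (final) coupling parameters the Aβ-positive
#' population is the more scopolamine-sensitive (steeper negative slope);
#' switching off the Aβ40 benefit (`delta = 0`) reverses the ordering —
#' the amyloid-positive cells are then pushed past the steep part of the
#' accuracy link, where further cholinergic insult moves accuracy less.
#'
#' @param doses Ascending scopolamine doses in nM (default 0-10 nM, 11
#'   points).
#' @param coupling A [coupling_params()] object.
#' @param cutoff Region cutoff in units (default 3).
#' @param params A [surrogate_params()] object.
#' @param receptor A [receptor_params()] object.
#' @param mode Partition mode, see [region_partition()].
#' @return A list of class `scop_dose_response`: `curve` (data.frame
#'   with `dose`, `region`, `accuracy`) and `slopes` (named vector, %
#'   correct per nM, `neg` and `pos`).
#' @export
#' @examples
#' \donttest{scopolamine_dose_response()$slopes}
scopolamine_dose_response <- function(doses = seq(0, 10, by = 1),
                                      coupling = coupling_presets("final"),
                                      cutoff = 3,
                                      params = surrogate_params(),
                                      receptor = receptor_params(),
                                      mode = "both-axes") {
  if (is.unsorted(doses) || any(doses < 0))
    stop("`doses` must be ascending and non-negative", call. = FALSE)
  part <- region_partition(cutoff, mode)
  st <- disease_state("MCI", 0, "APOE4+/-", params)
  base_no_chol <- 100 - .struct_deficit(st, params)
  # acute nicotinic drive changes relative to the zero-dose tone baseline
  cs0 <- cholinergic_state(st$cholinergic_tone, 0, receptor)
  region_acc <- function(cells, dose) {
    if (nrow(cells) == 0) stop("empty region", call. = FALSE)
    load <- abeta_load(cells$x, cells$y)
    g <- glu_conductance_factor(load, coupling)
    a7 <- a7_activation_factor(load, coupling)
    cs <- cholinergic_state(st$cholinergic_tone, dose, receptor)
    dh7 <- cs$a7_drive / cs0$a7_drive - 1
    dh4 <- cs$act_a4b2 / cs0$act_a4b2 - 1
    g_eff <- g * (1 + receptor$k_a7_glu * a7 * dh7 - receptor$k_gaba_glu * dh4)
    amy <- params$sens_mci * .amyloid_deficit(g_eff, a7, params)
    chol <- .chol_term(st$cholinergic_tone, dose, params, receptor)
    mean(accuracy_from_reserve(base_no_chol + chol + amy, params))
  }
  curve <- do.call(rbind, lapply(doses, function(d) {
    data.frame(dose = d, region = c("neg", "pos"),
               accuracy = c(region_acc(part$neg_cells, d),
                            region_acc(part$pos_cells, d)))
  }))
  ols_slope <- function(region) {
    dat <- curve[curve$region == region, ]
    stats::lm.fit(cbind(1, dat$dose), dat$accuracy)$coefficients[2]
  }
  structure(list(curve = curve,
                 slopes = c(neg = unname(ols_slope("neg")),
                            pos = unname(ols_slope("pos")))),
            class = "scop_dose_response")
}

#' @export
print.scop_dose_response <- function(x, ...) {
  cat("Scopolamine dose-response (2-back accuracy, MCI regions)\n")
  cat(sprintf("  fitted slopes: Abeta- %.3f, Abeta+ %.3f %% correct per nM\n",
              x$slopes[["neg"]], x$slopes[["pos"]]))
  invisible(x)
}
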