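#' Cholinergic receptor pharmacology parameters
#'
#' Equilibrium competitive-binding constants for the scopolamine
#' challenge. Scopolamine competes with acetylcholine (ACh) at the
#' postsynaptic M1 and the presynaptic M2 muscarinic receptor with the
#' published inhibition constants (Ki 1.1 and 1.22 nM). The M2
#' autoreceptor provides negative feedback on ACh release, so blocking it
#' raises synaptic ACh (gain `gamma`); the elevated ACh in turn modulates
#' alpha7 and alpha4beta2 nicotinic activation through saturating
#' half-activation constants. The free constants (half-activation
#' constants, `gamma`, `gaba_coupling`, baseline ACh) are not printed for
#' the underlying network; they were calibrated once so that the default
#' scopolamine dose-response slopes in the MCI populations fall near the
#' published -1.08 / -1.36 percent-correct-per-nM values, and are shipped
#' here as defaults.
#'
#' @param Ki_M1,Ki_M2 Scopolamine inhibition constants at M1/M2 (nM).
#' @param K_ACh_M1,K_ACh_M2 ACh half-activation constants at M1/M2 (nM).
#' @param gamma M2-autoreceptor feedback gain (dimensionless, >= 0).
#' @param K_a7,K_a4b2 Nicotinic half-activation constants (nM).
#' @param gaba_coupling Gain of alpha4beta2-driven GABA (inhibitory tone)
#'   relative to the M1 weight in the cognitive surrogate.
#' @param ach_base Baseline synaptic ACh concentration (nM) at normal
#'   cholinergic tone.
#' @param k_a7_glu,k_gaba_glu Gains of the acute nicotinic modulation of
#'   glutamate release under a pharmacological challenge: the alpha7
#'   channel facilitates release (scaled by the cell's amyloid-dependent
#'   alpha7 activation factor), the alpha4beta2-GABA channel suppresses
#'   it. Chronic tone changes are assumed homeostatically compensated, so
#'   these gains act on acute drug-induced drive changes only.
#' @return An object of class `receptor_params`.
#' @export
receptor_params <- function(Ki_M1 = 1.1, Ki_M2 = 1.22,
                            K_ACh_M1 = 50, K_ACh_M2 = 30,
                            gamma = 0.4,
                            K_a7 = 120, K_a4b2 = 80,
                            gaba_coupling = 0.3,
                            ach_base = 100,
                            k_a7_glu = 0.05, k_gaba_glu = 0.12) {
  vals <- list(Ki_M1 = Ki_M1, Ki_M2 = Ki_M2, K_ACh_M1 = K_ACh_M1,
               K_ACh_M2 = K_ACh_M2, gamma = gamma, K_a7 = K_a7,
               K_a4b2 = K_a4b2, gaba_coupling = gaba_coupling,
               ach_base = ach_base, k_a7_glu = k_a7_glu,
               k_gaba_glu = k_gaba_glu)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("`", nm, "` must be a single finite number", call. = FALSE)
  }
  if (gamma < 0) stop("`gamma` must be >= 0", call. = FALSE)
  if (any(unlist(vals[c("Ki_M1", "Ki_M2", "K_ACh_M1", "K_ACh_M2",
                        "K_a7", "K_a4b2", "ach_base")]) <= 0))
    stop("binding and half-activation constants must be > 0", call. = FALSE)
  structure(vals, class = "receptor_params")
}

#' @export
print.receptor_params <- function(x, ...) {
  cat("Cholinergic receptor parameters\n")
  cat(sprintf("  scopolamine Ki: M1 %.3g nM, M2 %.3g nM\n", x$Ki_M1, x$Ki_M2))
  cat(sprintf("  ACh K: M1 %.3g, M2 %.3g, a7 %.3g, a4b2 %.3g nM; baseline ACh %.3g nM\n",
              x$K_ACh_M1, x$K_ACh_M2, x$K_a7, x$K_a4b2, x$ach_base))
  cat(sprintf("  M2 feedback gamma %.3g; GABA coupling %.3g\n",
              x$gamma, x$gaba_coupling))
  invisible(x)
}

#' Muscarinic receptor activation under competitive scopolamine binding
#'
#' Equilibrium competition between ACh and scopolamine:
#' `act = ach / (ach + K_ACh * (1 + scop / Ki))`.
#'
#' @param ach Synaptic ACh concentration (nM, >= 0); vectorised.
#' @param scop Scopolamine concentration (nM, >= 0); vectorised.
#' @param receptor `"M1"` or `"M2"`.
#' @param params A [receptor_params()] object.
#' @return Activation fraction in `[0, 1]`.
#' @export
#' @examples
#' p <- receptor_params()
#' muscarinic_activation(p$K_ACh_M1, 0, "M1", p)  # 0.5
muscarinic_activation <- function(ach, scop, receptor = c("M1", "M2"),
                                  params = receptor_params()) {
  receptor <- match.arg(receptor)
  if (any(ach < 0) || any(scop < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  K <- if (receptor == "M1") params$K_ACh_M1 else params$K_ACh_M2
  Ki <- if (receptor == "M1") params$Ki_M1 else params$Ki_M2
  ach / (ach + K * (1 + scop / Ki))
}

#' Synaptic ACh elevation through M2-autoreceptor blockade
#'
#' The presynaptic M2 autoreceptor feeds back negatively on ACh release.
#' Blocking it with scopolamine disinhibits release; the ACh multiplier is
#' evaluated in one pass (no fixed-point iteration) as
#' `1 + gamma * (act_M2(0) - act_M2(scop)) / act_M2(0)`, which is 1 at
#' zero dose and tends to `1 + gamma` at full blockade.
#'
#' @param scop Scopolamine concentration (nM, >= 0); vectorised.
#' @param baseline_tone Relative cholinergic tone (1 = normal; the AD
#'   deficit is 0.7, the MCI compensation 1.3). Baseline ACh is
#'   `ach_base * baseline_tone`.
#' @param params A [receptor_params()] object.
#' @return ACh multiplier (>= 1), relative to the same tone at zero dose.
#' @export
ach_level_with_m2_feedback <- function(scop, baseline_tone = 1,
                                       params = receptor_params()) {
  if (any(scop < 0)) stop("`scop` must be non-negative", call. = FALSE)
  ach0 <- params$ach_base * baseline_tone
  act0 <- muscarinic_activation(ach0, 0, "M2", params)
  if (act0 <= 0)
    stop("baseline M2 activation is zero; check tone and K_ACh_M2", call. = FALSE)
  acts <- muscarinic_activation(ach0, scop, "M2", params)
  1 + params$gamma * (act0 - acts) / act0
}

#' Nicotinic receptor activation
#'
#' Saturating activation of alpha7 and alpha4beta2 nicotinic receptors in
#' the effective ACh concentration. The alpha7 output is multiplied by the
#' amyloid-dependent relative activation factor, so alpha7 is silenced at
#' `a7_factor = 0` regardless of ACh.
#'
#' @param ach_multiplier Effective ACh relative to `ach_base` (tone times
#'   any M2-feedback elevation); > 0.
#' @param a7_factor Amyloid-driven relative alpha7 activation in `[0, 1]`
#'   (see [a7_activation_factor()]).
#' @param params A [receptor_params()] object.
#' @return List with `act_a7` and `act_a4b2`, fractions in `[0, 1]`.
#' @export
nicotinic_activation <- function(ach_multiplier, a7_factor = 1,
                                 params = receptor_params()) {
  if (any(ach_multiplier <= 0)) stop("`ach_multiplier` must be > 0", call. = FALSE)
  if (any(a7_factor < 0) || any(a7_factor > 1))
    stop("`a7_factor` must lie in [0, 1]", call. = FALSE)
  ach <- params$ach_base * ach_multiplier
  list(act_a7 = a7_factor * ach / (ach + params$K_a7),
       act_a4b2 = ach / (ach + params$K_a4b2))
}

#' Cholinergic activation state relative to normal tone
#'
#' Convenience wrapper evaluating the whole cholinergic chain at a given
#' tone and scopolamine dose, and expressing each activation as a percent
#' change from the normal reference (tone 1, no drug, no amyloid).
#'
#' @param tone Relative cholinergic tone.
#' @param scop Scopolamine concentration (nM); vectorised.
#' @param params A [receptor_params()] object.
#' @return A data.frame with columns `scop`, `ach_multiplier`, `act_m1`,
#'   `act_a4b2`, `a7_drive` (the ACh-driven alpha7 saturation term,
#'   amyloid factor excluded) and the percent deviations `m1_pct`,
#'   `gaba_pct`, `a7_ach_pct`.
#' @export
cholinergic_state <- function(tone = 1, scop = 0, params = receptor_params()) {
  mult <- ach_level_with_m2_feedback(scop, tone, params)
  ach <- params$ach_base * tone * mult
  ref_ach <- params$ach_base
  act_m1 <- ach / (ach + params$K_ACh_M1 * (1 + scop / params$Ki_M1))
  ref_m1 <- ref_ach / (ref_ach + params$K_ACh_M1)
  a7_drive <- ach / (ach + params$K_a7)
  ref_a7 <- ref_ach / (ref_ach + params$K_a7)
  act_a4b2 <- ach / (ach + params$K_a4b2)
  ref_a4b2 <- ref_ach / (ref_ach + params$K_a4b2)
  data.frame(scop = scop, ach_multiplier = tone * mult,
             act_m1 = act_m1, act_a4b2 = act_a4b2, a7_drive = a7_drive,
             m1_pct = 100 * (act_m1 / ref_m1 - 1),
             gaba_pct = 100 * (act_a4b2 / ref_a4b2 - 1),
             a7_ach_pct = 100 * (a7_drive / ref_a7 - 1))
}
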