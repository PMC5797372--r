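---
title: "The abqsp amyloid-cognition model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The abqsp amyloid-cognition model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abqsp)
```

This vignette documents the science and the design of `abqsp`: the
coupling model between low-order amyloid-beta aggregates and synaptic
function, the reduced-form cognitive surrogate and its calibration, the
receptor pharmacology behind the scopolamine challenge, the virtual-trial
arithmetic, and the choices we made where the design was genuinely open.

## 1. The amyloid coupling model

Aβ40 load $x$ and Aβ42 load $y$ live on a 17 × 17 integer grid
(0–16 model units per axis). One unit is the amyloid accrued in 13 weeks
by an APOE4+/− placebo patient; the SUVR map `suvr_map()` anchors 0
units to florbetapir SUVR 1.0 and 3 units to SUVR 1.34, linearly.
Two couplings act on neurotransmission:

* **NMDA conductance** (biphasic in Aβ40, monotone in Aβ42), with peak
  position `x0` (default 2 units), maximal relative benefit `delta`,
  post-peak decline `alpha` and Aβ42 slope `alpha_star` (all per unit).
  The benefit branch is evaluated as $\delta\,x/x_0$; when `x0 = 0` the
  peak sits at the origin and only the declining branch is used, which
  avoids the division by zero. The result is floored at 0 and has no
  ceiling.
* **α7 nicotinic activation**, $\max(0,\,1-\beta(x+y))$, with a single
  coupling factor `beta` for both isoforms.

Two parameter presets are used throughout (`coupling_presets()`): the
*MCI-calibration* set (`delta` 0.015, `alpha` 0.0015, `alpha_star`
0.00035, `beta` 0.025) under which the MCI region averages were derived,
and the *final* set (`delta` 0.025, `alpha` = `alpha_star` = 0.002,
`beta` 0.03) retained for the intervention analyses.

Clinical populations are defined by a region partition at a cutoff
(default 3 units): Aβ− is the box $x,y<3$ (9 cells), Aβ+ the box
$x,y\ge 3$ (196 cells). The partition text convention excludes mixed
cells; a `complement` mode treats Aβ+ as everything outside the Aβ− box,
because the pipeline-figure caption supports that reading. Both are
exposed; `both-axes` is the default.

## 2. The cognitive surrogate

The original analyses ran a biophysically detailed cortical network; that
network is defined in prior work and is not reproducible from the
present description. `abqsp` replaces it with a calibrated reduced form —
a latent *network reserve* mapped to the two cognitive readouts:

$$R = 100 - P_0 - c_{syn}\,d_{syn} - c_{neu}\,d_{neu} + C(\text{tone},
\text{scop}) + s(\text{stage}, t, \text{geno})\cdot A(g, \alpha_7),$$

where $d_{syn}, d_{neu}$ are percent density deficits, $C$ the
cholinergic term, $s$ a stage/week/genotype sensitivity multiplier and
$A$ the amyloid response

$$A = a_{ben}\left(1-e^{-g^+/s_{glu}}\right)
    - a_{def}\left(1-e^{-(g^-/s_{glu})^{h}}\right)
    - w_{\alpha7}\, c_{\alpha7}\left(1-e^{-D/s_{\alpha7}}\right),$$

with $g^\pm$ the positive/negative percent conductance change and $D$
the percent α7 activation loss. The saturating forms matter: the concave
α7 cost makes small early activation losses disproportionately costly
(this is what produces realistic Aβ− MCI averages at loads of only 1–2
units), while the Hill-onset conductance cost distinguishes populations
of moderate, uniform losses from mixtures of benefits and deep losses.
The α7 arm is weighted by stage ($w_{\alpha7}=1$ in MCI, 0.15 in AD):
under the MCI cholinergic compensation the α7–glutamate channel has
leverage on cognition, whereas in AD, with a 30% cholinergic deficit,
its contribution is much more limited than the glutamatergic arm.

**Links.** Reserve maps to ADAS-Cog through an asymmetric Richards-type
logistic bounded by the instrument range $[0, 70]$,
$\mathrm{ADAS} = 70\,(1-(1-p)^{\nu})$ with
$p=\mathrm{logit}^{-1}(k(R_{50}-R))$. With shape $\nu<1$ the inflection
sits in the mild-to-moderate AD range, so the link is convex over the
MCI range (needed to reproduce the steep worsening of the Aβ+ MCI
average when the Aβ40 benefit is removed) and mildly concave above
(needed to keep the three APOE trajectories near-parallel). A symmetric
logistic cannot do both, which is why the shape parameter exists.
Accuracy on the 2-back working-memory task uses a plain logistic in
reserve, increasing, bounded $[0, 100]$; its midpoint sits at an
intermediate impairment level, so cognitive sensitivity to any insult
peaks at moderate pathology and saturates beyond — the mechanism behind
the scopolamine slope reversal discussed below.

**Disease states.** MCI: 3% synapse and neuron density decrement,
cholinergic tone 1.3 (compensation). AD: baseline densities 0.90/0.85
plus a pathology offset $P_0$, linear losses of 0.04%/week (synapses)
and 0.35%/week (neurons), tone 0.7. APOE scales synapse density by 1.2 /
1.0 / 0.8 (−/−, +/−, +/+), and scales amyloid deposition 0.5 / 1.0 / 1.5
units per 13 weeks.

**Path accumulation.** In virtual trials the amyloid term is accumulated
incrementally along the load trajectory,
$\sum_t s(t)\,\Delta A(t)$, with $s(t)$ interpolated between the
evaluation weeks, rather than evaluated from the final state alone. The
week-indexed sensitivities are clinical anchors (about 0.65 ADAS points
per % conductance at weeks 12–26, 0.4 at weeks 52–78, intermediate at
week 0), and the incremental form is the reading under which amyloid
changes over a time span translate into ADAS-Cog changes at the
sensitivity prevailing when they occur. A purely state-based readout
cannot reproduce any treatment disadvantage at low baseline loads, since
a treated arm's final state dominates placebo's there.

## 3. Calibration

`calibrate_surrogate()` is staged and fully deterministic:

1. **MCI block** (`nlminb`, weighted least squares): link curvature $k$,
   shape $\nu$ and the five amyloid-response constants are fitted to the
   MCI region-average anchors — the primary pair 7.4/10.4 (Aβ−/Aβ+,
   cutoff 3, MCI-calibration set, weight 3), the auxiliary pair 7.8/10.7
   attributed to the final set, and the rejected-branch `delta = 0`
   variant 8.4/14.2 (weight 1 each). The healthy-control anchor
   (ADAS 4.5 at reserve 100) and the zero-amyloid MCI anchor (4.1) are
   enforced exactly through the link at every candidate. Box bounds keep
   the fit identifiable: $k \in [0.03, 0.4]$, $\nu \in [0.2, 1]$,
   response scales within the range the couplings can actually produce
   (e.g. $s_{glu} \ge 0.8$% — sharper saturation degenerates into a step
   that destabilises the week-sensitivity solve).
2. **AD block** (fixed-point iteration to $10^{-10}$): the synapse
   weight from the 2-point APOE week-0 gap, the neuron weight from the
   9.25-point 78-week placebo worsening (centre of the 8.5–10 range),
   the pathology offset from the 21-point heterozygote baseline, the
   cholinergic weight from the zero-amyloid MCI anchor, and the five
   week sensitivities solved exactly against the same 1% finite
   difference that `glu_slope()` reports. About six iterations converge.
3. **Accuracy link**: midpoint placed at the reserve of ADAS 20 (so both
   MCI regions sit on the upper, responsive branch) and steepness solved
   by `uniroot` so the mean absolute scopolamine slope equals 1.22%/nM,
   the centre of the published −1.08/−1.36 pair.

The result ships in `inst/params/surrogate-params.yaml` together with
every anchor's target, achieved value and residual;
`surrogate_params(refit = TRUE)` reproduces it to optimizer precision.
All primary anchors are met essentially exactly; the auxiliary
final-set Aβ+ average carries the largest residual (about +1.4 points),
the price of simultaneously matching the `delta = 0` branch — the three
Aβ+ targets over-determine any smooth response family we tried.

## 4. Receptor competition and the scopolamine challenge

Scopolamine competes with ACh at equilibrium:
$\mathrm{act} = \mathrm{ACh}/(\mathrm{ACh} + K(1+\mathrm{scop}/K_i))$
with the published $K_i$ of 1.1 nM (M1) and 1.22 nM (M2). Blocking the
presynaptic M2 autoreceptor disinhibits ACh release (one-pass gain
$\gamma$, multiplier $\to 1+\gamma$ at full blockade); the elevated ACh
drives α7 and α4β2 through saturating half-activation constants. Acute
nicotinic drive changes also modulate glutamate release: facilitation
through α7 (scaled by the cell's amyloid-damaged α7 factor) against
suppression through α4β2-driven GABA, both relative to the zero-dose
tone baseline (chronic tone shifts are assumed homeostatically
compensated; an acute pharmacological challenge is not). The net
modulation is small and inhibitory, and its cognitive impact per cell is
amplified by the local slope of the saturating conductance response.

That amplification is what orders the dose–response slopes. With the
final coupling set, Aβ+ cells sit near the steep onset of the
conductance cost while Aβ− cells sit on the flat benefit side, so the
Aβ+ population is the more scopolamine-sensitive. Setting `delta = 0`
moves the Aβ− cells onto the steepest part of the cost curve and pushes
the Aβ+ population into the saturated region of the accuracy link, and
the ordering reverses. The free constants (half-activation constants,
$\gamma$, the two glutamate-modulation gains, baseline ACh 100 nM) are
not printed for the underlying network; they were calibrated once so the
default slopes land near the published values, then frozen as shipped
defaults. The default dose grid is 0–10 nM in 1-nM steps; the grid is
not printed either, and ordinary least squares over the curve defines
the reported slope.

## 5. The virtual-trial engine

Loads grow linearly, `load(t) = start + rate * t/13` per axis, clamped
at the 16-unit grid ceiling with a warning. Treated arms keep their
baseline load (reductions act on accrual only; steady-state
pharmacology from week 0). Effects are read from the matrix through the
mass-conserving three-point quadrature: with support $\{m-1,m,m+1\}$ and
effective load $L$, the weights $1/3+(m-L)/2$, $1/3$, $1/3-(m-L)/2$ are
the unique solution to (sum 1, centre weight 1/3, mass mean $L$), and
they reproduce any affine function of the loads exactly. For treated
arms the window is anchored at the placebo destination cell — the only
anchoring that reproduces the published 0.73/0.33/−0.06 weighting for
the low-dose BACE-I case — with negative weights acting as linear
extrapolation; at the grid edges the window shifts inward, keeping the
mass-mean constraint. Trials are patient-matched: the identical cohort
runs on every arm, and contrasts are reported as points better than
placebo. Paths are simulated at weekly resolution (79 steps) and read
out at the evaluation weeks 0, 12, 26, 52, 78.

## 6. The sensitivity scan

`evaluate_conditions()` evaluates the three clinical constraints for one
coupling-parameter set: (c1) some integer cutoff below 4 puts the Aβ−
MCI average within 8.5 ± 1 and the Aβ+ average within 10.7 ± 1; (c2) the
Aβ+ population is the more scopolamine-sensitive at cutoff 3; (c3) the
three APOE trajectory slopes stay within 10% relative spread while the
week-0 APOE4+/+ vs APOE4−/− gap is at least 1.5 points. `grid_scan()`
maps them over a 7 × 5 × 5 × 4 grid (700 cells) spanning every quoted
parameter value, at fixed `x0`; the scan is a pure map (cell order is
irrelevant) and takes about half a minute on one CPU. In the shipped
calibration no `delta = 0` cell satisfies all three conditions — the
package's reproduction of the headline claim that a neurostimulatory
Aβ40 dose range is necessary — and condition 2 passes increasingly often
as `delta` grows. The surrogate does not, however, confine the
all-three region to `delta > 0.02` and `alpha + alpha* > 0.003`: that
exact frontier is a knife-edge property of the original network's
nonlinearity (the condition-1 band edges pass within about 0.1 ADAS
points of the computed averages), and a reduced surrogate calibrated to
the printed anchors reproduces the mechanism but not the precise line.
The same limitation applies to treatment contrasts at *low* baseline
loads: under the coupling equations a treated arm's week-78 state
dominates placebo's there, and with the published week-sensitivity
ratios the path integral retains too little memory of placebo's
transient mid-trial advantage to end negative, so `abqsp` shows
near-neutral rather than adverse low-baseline effects (the
high-baseline benefits, their drug-class ordering and their saturation
with baseline load are reproduced).

## 7. Synthetic cohorts

`generate_cohort()` draws virtual patients — id, APOE genotype, baseline
load — from a `cohort_spec()`: fixed baselines, uniform draws over a
partition region, or an arbitrary discrete bivariate table. The default
genotype mix is 0.25/0.50/0.25 (no mix is stated for the original
cohorts; this symmetric default is configurable). Measurement noise is
additive Gaussian on ADAS-Cog only, clipped to [0, 70], applied after
simulation (`add_measurement_noise()`); the mechanistic model itself is
deterministic, so noise exists to exercise cohort-level statistics, and
everything is reproducible from a single seed. What the generator does
*not* emulate: demographic covariates, dropout, comorbidity,
within-patient measurement correlation, or any realistic joint
distribution of baseline load and genotype — passing tests on these
cohorts shows the pipeline arithmetic is right, not that real trial
data would behave this way.

## 8. Numerical choices and degenerate inputs

Quadrature identities hold to $10^{-12}$ and are tested at that
tolerance. Loads outside [0, 16] and probabilities not summing to 1
(tolerance $10^{-9}$) are rejected with named errors. `x0 = 0` uses the
declining branch only. Activation floors are hard zeros; the α7 factor
sampled with extrapolating weights is clipped back to [0, 1] before it
enters the surrogate. Region partitions at cutoff 1 reduce the Aβ− box
to the origin cell; empty regions raise errors. The calibration
optimizer runs from fixed starting values with box bounds, so repeated
fits are bit-identical; the fixed-point stage stops at $10^{-10}$ or 12
iterations. Trial paths use weekly steps; evaluation weeks must be
integers in [0, 78].

## 9. Known limitations

The surrogate is a stand-in for a biophysical network: its anchors are
reproduced by construction (the MCI region averages are
calibration-consistency checks, not predictions), and only the
qualitative structure — orderings, reversals, sign patterns, the
`delta = 0` exclusion — constitutes an independent test surface. The
exact sensitivity-analysis frontier and adverse low-baseline treatment
effects are not reproduced (section 6). Antibody pharmacology is a
simple fractional reduction of deposition (no aggregation-pathway
mechanism, no Aβ rebound for gamma-secretase inhibition); scopolamine
has no pharmacokinetics (sensitivity is a dose–response slope); there is
no co-medication, no tau or vascular pathology, and no spatial or
tracer-affinity component in the SUVR map.
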