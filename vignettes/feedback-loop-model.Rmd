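---
title: "The autophagy–α-catenin–YAP/TAZ feedback loop: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The autophagy–α-catenin–YAP/TAZ feedback loop: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catloop)
```

## The biological question

YAP/TAZ are the transcriptional effectors of the Hippo pathway: nuclear
YAP/TAZ drives TEAD-dependent transcription and proliferation, cytoplasmic
YAP/TAZ is inactive. Macroautophagy perturbations have been reported to
push YAP/TAZ in *opposite* directions in different cell lines — inhibition
of autophagy lowers YAP/TAZ activity in some epithelial lines (MCF10A-like
behaviour) and raises it in others (HepG2-like behaviour). Two mechanisms
pull in opposite directions: autophagy degrades YAP/TAZ directly, and it
also degrades α-catenin, a junctional protein that sequesters YAP/TAZ in
the cytosol and binds LC3 through LIR motifs. Which mechanism wins depends
on how much α-catenin a cell starts with.

`catloop` packages a minimal dynamical model of this competition, the
analyses that turn it into a testable regime logic (direction
classification, flip-boundary location, time-windowed correlations), a
synthetic-readout generator with known ground truth, estimators that
recover the regime from noisy readouts, and a scanner for the LIR core
consensus.

## The model

Three dimensionless state variables: autophagy level $A$, YAP/TAZ activity
$Y$, α-catenin level $C$.

$$\frac{dA}{dt} = -cA - v_Y\left(1 - e^{-\delta_A Y}\right)A$$
$$\frac{dY}{dt} = -r_1 Y C + r_2\left(1 - e^{-\delta_Y A}\right)\left(1 - \frac{Y}{Y_{\max}}\right)Y$$
$$\frac{dC}{dt} = r_3 v_C v_Y \left(1 - e^{-\delta_C A}\right)\left(1 - \frac{C}{C_{\max}}\right)C$$

Each term is one action. $-cA$ is the primary inhibition being modelled
(genetic or chemical); $-v_Y(1-e^{-\delta_A Y})A$ is the loss of
YAP/TAZ-driven autophagosome formation, saturating so that only strong
YAP/TAZ depletion matters; $-r_1 Y C$ is sequestration of YAP/TAZ by
α-catenin; the $r_2$ term is the autophagy-dependent accumulation of
YAP/TAZ activity, logistic in $Y$ up to $Y_{\max}$; the $C$ equation
accumulates α-catenin (an autophagy substrate) towards $C_{\max}$, at a
rate proportional to its own initial level. Protein synthesis is neglected.
Model time is dimensionless; no mapping to wall-clock hours is asserted
anywhere in the package, because none is defined for the model.

The scales are derived from the initial state, not free:
$v_C = k\,C(0)$, $C_{\max} = k_C\,C(0)$, $Y_{\max} = k_Y\,Y(0)$. The
source description of the YAP ceiling is typeset as "$k_Y(0)$"; `catloop`
reads it as $k_Y \cdot Y(0)$, the only interpretation under which the
ceiling scales with the initial activity the way $C_{\max}$ scales with
$C(0)$. All three are recomputed per run from that run's own initial
state, including per cell inside parameter sweeps.

### Parameters and defaults

| Parameter | Meaning | Default |
|---|---|---|
| `c` | primary autophagy depletion rate | 0.1 |
| `r1` | YAP/TAZ sequestration rate by α-catenin | 1.0 |
| `r2` | YAP/TAZ accumulation rate | 1.2 |
| `r3` | α-catenin accumulation rate | 3.0 |
| `k`, `k_C`, `k_Y` | scale factors for $v_C$, $C_{\max}$, $Y_{\max}$ | 1, 3, 4 |
| `delta_A`, `delta_Y`, `delta_C` | saturation exponents | 1 |
| `v_Y` | feedback strength (YAP/TAZ → autophagy) | 0.5 |

All quantities are dimensionless. The reference initial state is
$A(0) = Y(0) = 1$; $C(0)$ ("α-cat") is the quantity of interest, expressed
relative to a high-α-catenin reference line pinned at 1. `v_Y = 0` is
accepted as the no-feedback limiting case; all other constants must be
strictly positive.

## Numerical choices

- **Integrator.** Adaptive Dormand–Prince Runge–Kutta (`deSolve`,
  method `"ode45"`) at `rtol = 1e-8`, `atol = 1e-10`. The system is not
  stiff in the explored parameter ranges; the tolerances are chosen so
  that the solution agrees with an independent fixed-step RK4 integration
  to better than $10^{-6}$ in sup norm over $t \in [0, 10]$, which the
  test suite verifies on random parameter draws.
- **Output grid.** Equally spaced dense output (default 400 samples),
  decoupled from the internal adaptive steps, so correlation windows and
  horizon look-ups are well defined and refinable.
- **Positivity.** The exact solution is non-negative; sub-tolerance
  negative overshoot from the stepper (below $10^{-8}$ in magnitude) is
  clamped to zero, and anything larger raises an error instead of being
  silently absorbed.
- **Degenerate $C(0) = 0$.** Then $v_C = C_{\max} = 0$ and the $C$
  equation is identically zero; the implementation returns $dC = 0$
  directly rather than evaluating the indeterminate $1 - C/C_{\max}$.
- **Ties.** The "unchanged" direction band is $|Y(T)/Y(0) - 1| \le$
  `tie_eps` $= 10^{-6}$, far below integrator error visibility, so the
  label is effectively a sign read-out of $Y(T) - Y(0)$.

## The regime logic and its calibrated horizon

`classify_direction()` compares $Y(T)$ with $Y(0)$ at a finite horizon
$T$; `find_flip_boundary()` bisects the initial α-catenin for the root of
$Y(T) - Y(0)$ (default bracket $[0.05, 1.0]$, tolerance $10^{-4}$). The
boundary is a finite-horizon classification boundary, not a fixed-point
bifurcation — no continuation analysis is attempted.

The horizon is not part of the model; it stands in for "the experimentally
relevant duration of the perturbation", which the underlying study leaves
unquantified. Because α-catenin accumulates monotonically, the boundary
drifts downward as $T$ grows (`flip_boundary_profile()` tabulates this).
`catloop` fixes the default at $T = 2.5$ model-time units, the choice
under which the classification boundary at the reference feedback
strength $v_Y = 0.5$ falls inside the empirically characterised band:
basal CTNNA1 ratios above 0.5 behave as the decrease regime and ratios
around 0.3 or below as the increase regime, so the flip must sit between
0.3 and 0.5. Longer horizons (e.g. $T = 3$) push the boundary below 0.3
and would misclassify the low-regime band edge. Both $T$ and $v_Y$ remain
explicit arguments everywhere, and the sensitivity table is exported
precisely because conclusions near the band edges depend on them.

```{r boundary, eval = FALSE}
find_flip_boundary(model_params(), initial_state(), v_Y = 0.5, T = 2.5)
flip_boundary_profile(T_values = c(2, 2.5, 3))
```

## Time-windowed correlations

In the low-α-catenin regime the trajectory is biphasic: $Y$ first rises
while $A$ falls (degradation relief dominates), then — once accumulated
α-catenin crosses the level where sequestration dominates — $Y$ falls
together with $A$. The qualitative changepoint is the $Y$ maximum, and it
is the only changepoint the model produces, so
`windowed_correlation()` splits the sample grid at the sampled $Y$ peak
(peak sample included in both windows, ties broken to the earliest
sample) and reports the Pearson correlation of $(Y_i, A_i)$ per window,
unweighted on the equally spaced grid — the same reading one would take
off a plotted trajectory pair. Windows with zero variance raise an
undefined-correlation error; a peak at either end of the grid (the
monotone high-α-catenin regime) yields a one-sided result with a
diagnostic instead of an error.

## What the synthetic panels emulate — and what they do not

`generate_panel()` mimics the *measurement design* of the cell-line
experiments: per-line basal CTNNA1 densitometry ratios relative to a
reference line ("MCF10A_like", pinned at a true relative level of 1.0),
CTNNA1 after autophagy knockdown, and TEAD luciferase (firefly/renilla)
activity as the YAP/TAZ proxy, in 3–6 replicates per condition. High-regime
lines draw their true basal level uniformly from $[0.5, 1.2]$ and
low-regime lines from $[0.05, 0.3]$, mirroring the two observed classes of
basal ratios.

Replicate noise is multiplicative lognormal with default CV 0.2 — a
deliberate modelling choice: densitometry and luciferase ratios are
positive and their spread scales with the mean, and a CV of 20% is a
realistic replicate spread for such assays. Readout centres are the
distribution medians, so geometric-mean estimators are unbiased on the
log scale. The knockdown condition *is* the default model scenario (the
$-cA$ term is the inhibition); "autophagy induction" is represented by an
elevated initial autophagy level (default $A(0) = 2$), because the model
has no induction input term — the initial-state sweep is the only
mechanism it offers for raised autophagy.

Passing tests on these panels therefore demonstrate that the inference
machinery is correct *under the model's own forward map with lognormal
noise*. They do not validate the noise family against real densitometry,
nor capture blot saturation, loading-control error, batch effects, or
any mapping from model time to assay time — none of which the package
claims to model.

## Inference

`estimate_alpha_init()` is the ratio of geometric means (line over
reference) of baseline CTNNA1 replicates — the estimator matched to
multiplicative noise. With baseline data alone, `v_Y` is reported as
not identifiable (NA) rather than as a number.
`fit_timecourse()` couples the forward model to a TEAD time series by
least squares on log residuals, box-constrained to
$C(0) \in [0.01, 2]$, $v_Y \in [0.05, 1.5]$ (L-BFGS-B); estimates pinned
at a bound, or a non-zero optimiser status, are flagged in the
diagnostics. `predict_direction()` runs the forward model at the
estimate; estimates falling inside the empirically unresolved basal band
$(0.3, 0.5)$ are additionally labelled `indeterminate` rather than forced
into a regime, since neither observed cell-line class sits there.

Problem sizes used in the shipped tests — 10 lines per regime, 4
replicates at CV 0.2, 100–500 Monte-Carlo repeats for estimator
calibrations, RK4 oracle steps of $10^{-3}$–$10^{-4}$ — were chosen to
give stable verdicts for these statistics; the frozen error tolerance of
the basal estimator (median absolute error < 0.05 at CV 0.2, $n = 4$) was
fixed from an independent Monte-Carlo run of the estimator before being
written into the tests.

## LIR scanning

`lir_scan()` applies only the core LIR consensus
$[\mathrm{WFY}]\,x\,x\,[\mathrm{ILV}]$ — the aromatic and hydrophobic
anchors of Atg8-family binding. Hits are reported in the hexamer
convention of LIR tables (two upstream flanking residues plus the
4-residue core, 1-based inclusive coordinates), so the aromatic anchor is
hexamer position 3 and the hydrophobic anchor position 6, directly
comparable with published candidate tables such as the six CTNNA1 regions
bundled in `ctnna1_lir_candidates()`. No position-specific scoring,
disorder filter, or structural (surface-accessibility) filter is applied:
scanning a full-length protein returns every consensus occurrence, which
is by construction a superset of any curated candidate list. The
experimentally mapped C-terminal LIR of CTNNA1 (QALSEF) is the standing
reminder that the consensus is not exhaustive — it binds LC3 without
matching the core pattern, and `check_lir_candidates("QALSEF")` reports
exactly that.

## Known limitations

- The model is deliberately minimal: no stochasticity, no delays, no
  synthesis terms, no explicit autophagy-induction input.
- The flip boundary and direction labels depend on the evaluation horizon
  and feedback strength; both are exposed, and the defaults are one
  calibrated choice, not measured constants.
- The narrative of the degradation-relief mechanism ("less autophagy,
  more YAP") and the functional form of the $r_2$ term (growth increasing
  with $A$) sit in tension; the equations are implemented exactly as
  stated, with the relief effect emerging from the balance of terms
  rather than from a negative dependence on $A$.
- Correlation window placement is defined by the model's $Y$ peak; other
  windowings of experimental time courses are not recoverable from the
  model and are out of scope.
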