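# catloop

Modelling the feedback loop between macroautophagy, α-catenin and YAP/TAZ.

Autophagy perturbations push YAP/TAZ transcriptional activity in opposite
directions in different cell lines. Two competing mechanisms explain this:
autophagy degrades YAP/TAZ directly (so inhibiting autophagy raises
activity), and autophagy also degrades α-catenin, a junctional LC3-binding
protein that sequesters YAP/TAZ in the cytosol (so inhibiting autophagy
lets α-catenin accumulate and lowers activity). Which mechanism wins is
set by how much α-catenin a cell starts with. `catloop` implements the
minimal dynamical model of this competition and the analyses that turn it
into a testable regime logic, for systems biologists who want to simulate,
sweep, and fit the loop rather than re-derive it.

## The model

Three coupled ODEs in dimensionless autophagy level *A*, YAP/TAZ activity
*Y* and α-catenin level *C*:

    dA/dt = -cA - v_Y (1 - e^(-δ_A Y)) A
    dY/dt = -r1 Y C + r2 (1 - e^(-δ_Y A)) (1 - Y/Y_max) Y
    dC/dt = r3 v_C v_Y (1 - e^(-δ_C A)) (1 - C/C_max) C

with scales derived from the initial state: `v_C = k·C(0)`,
`C_max = k_C·C(0)`, `Y_max = k_Y·Y(0)`. Default constants:
`c = 0.1, r1 = 1, r2 = 1.2, r3 = 3, k = 1, k_C = 3, k_Y = 4`, all δ = 1,
reference feedback strength `v_Y = 0.5`, initial state `A = Y = 1`.
`C(0)` ("α-cat") is a cell line's basal α-catenin relative to a
high-α-catenin reference line.

The package provides: trajectory integration (adaptive Dormand–Prince,
`deSolve`), response-surface sweeps over `(v_Y, α-cat)` and initial-state
grids, direction classification of the YAP/TAZ response with bisection of
the α-catenin flip boundary, time-windowed YAP–autophagy Pearson
correlations, a synthetic multi-cell-line readout generator (CTNNA1
densitometry and TEAD luciferase proxies with lognormal replicate noise),
estimators recovering basal α-catenin and feedback strength from such
panels, and a scanner for the LIR core consensus `[WFY]xx[ILV]`.

## Worked example

```r
library(catloop)

# Where does the YAP/TAZ response flip from increase to decrease?
find_flip_boundary(model_params(), initial_state(), v_Y = 0.5, T = 2.5)$boundary
#> [1] 0.3213333

# Low-basal-α-catenin line under autophagy inhibition: biphasic response
traj <- integrate_model(model_params(v_Y = 0.5),
                        initial_state(alpha_cat_init = 0.1), t_end = 10)
windowed_correlation(traj)[c("R_early", "R_late", "t_peak")]
#> $R_early
#> [1] -0.9951829
#> $R_late
#> [1] 0.8801734
#> $t_peak
#> [1] 3.358396

# The six CTNNA1 candidate LIR hexamers all match the core consensus
sum(check_lir_candidates(ctnna1_lir_candidates()$hexamer)$matches)
#> [1] 6
```

Reading: a cell line with basal α-catenin above 0.32 (relative to the
reference) responds to autophagy inhibition with a net *decrease* of
YAP/TAZ activity at the default horizon T = 2.5, below it with a net
*increase* — matching the two observed classes of cell lines (basal
CTNNA1 ratio > 0.5 versus ≲ 0.3). In the low-α-catenin regime, YAP/TAZ
first rises while autophagy falls (pre-peak Pearson R = −0.995), then
falls together with autophagy once accumulated α-catenin dominates
(post-peak R = 0.880).

The methods vignette (`vignettes/feedback-loop-model.Rmd`) documents the
model assumptions, the calibrated horizon, the noise model and the known
limitations.

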