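# bayestfm

Bayesian traction force estimation from sparse bead displacements in
traction force microscopy (TFM), for cell biologists and biophysicists who
need reliable force maps at realistic (low) bead densities.

In TFM, fluorescent beads on an elastic substrate move when a cell pulls on
it, and the traction field **f** must be recovered from the bead
displacements **u**. The forward model is the discretized Boussinesq
solution for an elastic half-space, **u** = G **f**, with

G̃(x) = (1−ν)/(πEr³) · [ ((1−ν)r² + νx² , νxy) ; (νxy , (1−ν)r² + νy²) ],

stacked over beads × force grid points with an A/N area weight (E: Young's
modulus, ν: Poisson ratio, A: cell area, N: grid points). With far fewer
bead displacements than force unknowns the inversion is ill-posed; generic
regularization (ridge, lasso) ignores where the cell is and what forces it
can plausibly exert.

This package implements a Bayesian estimator whose prior is built from the
individual cell boundary: prior force magnitude decays as exp(−r²/σ²) with
the inward distance r from the boundary (σ² = 10% of cell area), and prior
force direction is the inward gradient of the cell outline's signed-distance
level-set function after brief mean-curvature-flow smoothing. Per-point
rotation/scale corrections {θₙ, sₙ} with a sparsity (Laplace) prior on sₙ
are optimized jointly with the forces by coordinate ascent on the log
posterior

−(α/2)‖u − Gf‖² − (β/2)‖f − F_μ(θ, s)‖² − γΣ|sₙ| (α = 1, β = 0.1, γ = 0.01).

Ridge and lasso baselines (bead-wise cross-validation) run on the identical
forward model, and a synthetic benchmark generator plus ROC-AUC / DTM / DTMB
metrics reproduce the method's evaluation protocol end to end. See the
vignette `vignettes/traction-force-estimation.Rmd` for the model details
and numerical choices.

## Worked example

```r
library(bayestfm)

# a synthetic "cell": lobed boundary, 20 inward traction points,
# beads at 0.4 / um^2, observation noise sd 0.1 um
cfg <- tfm_config(shape = "blob", field_px = 96, bead_density = 0.4)
ds  <- make_dataset(cfg, seed = 1)
ds
#> <tfm_dataset> blob boundary, 20 force points, 147 beads (0.4 /um^2), noise sd 0.1 um

fit <- btfe(ds$beads, ds$mask, substrate = ds$substrate, grid = ds$grid,
            prior = ds$prior, prior_scale = cfg$force_magnitude, seed = 1)
fit
#> <btfe_fit> 900 force points, log MAP objective -1.093, iteration cap reached (5 restarts)

evaluate_estimate(fit, ds)
#> # A tibble: 1 x 5
#>     auc    dtm   dtmb m_pos m_neg
#>   <dbl>  <dbl>  <dbl> <int> <int>
#> 1 0.795 -0.709 0.0937    20   238

ridge <- tfm_baseline(ds$beads, ds$mask, "ridge", substrate = ds$substrate,
                      grid = ds$grid, seed = 1)
evaluate_estimate(ridge, ds)
#> # A tibble: 1 x 5
#>     auc    dtm   dtmb m_pos m_neg
#>   <dbl>  <dbl>  <dbl> <int> <int>
#> 1 0.734 -0.888 0.0444    20   238
```

The Bayesian fit detects the 20 true force points better than ridge
(AUC 0.80 vs 0.73 here), underestimates their magnitude far less
(DTM −0.71 vs −0.89), at the price of slightly larger — but still small —
false-positive background forces (DTMB 0.09 vs 0.04). `tidy(fit)`
returns the per-grid-point force table, `glance(fit)` the fit diagnostics,
and `autoplot(fit)` a quiver map of the estimated traction.

A shell entry point wrapping the same functions is installed at
`inst/cli/bayestfm.R` (subcommands `simulate`, `estimate`, `evaluate`,
`benchmark`).

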