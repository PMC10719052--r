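---
title: "Bayesian traction force estimation with cell-boundary priors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian traction force estimation with cell-boundary priors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bayestfm)
```

## The inverse problem

Traction force microscopy (TFM) infers the forces a cell exerts on its
substrate from the displacement of fluorescent beads embedded in the
substrate surface. For a linear, isotropic, homogeneous elastic half-space,
a tangential point force produces the surface displacement given by the
Boussinesq-Green tensor

$$G(\mathbf{x}) = \frac{1-\nu}{\pi E r^3}
\begin{pmatrix} (1-\nu)r^2 + \nu x^2 & \nu x y \\
\nu x y & (1-\nu)r^2 + \nu y^2\end{pmatrix}, \qquad r = |\mathbf{x}|,$$

with Young's modulus $E$ and Poisson ratio $\nu$ (default 0.5, an
incompressible gel). Discretizing the traction field on an $N$-point grid
over the image (default $30\times30$) gives the linear forward model
$\mathbf{u} = G\mathbf{f}$, where $G$ stacks $(A/N)\,G(\mathbf{x}_i -
\mathbf{x}'_n)$ blocks ($A$ = cell area), $\mathbf{f}$ interleaves the x/y
force components at the grid points and $\mathbf{u}$ the bead
displacements. With hundreds of beads and 1800 force unknowns the problem
is badly underdetermined: plain least squares is hopeless, ridge shrinks
everything toward small diffuse forces, and the lasso explains the data
with a few spikes wherever beads happen to sit — both ignore where the
cell actually is.

## The boundary prior

The estimator here uses two robust observations about motile cells:
traction is strongest near the cell edge (where actin polymerization and
retrograde flow couple to the substrate) and it points inward. Both are
encoded in a prior center field $\mathbf{f}_\mu(\mathbf{x}) =
m(\mathbf{x})\, \mathbf{d}(\mathbf{x})$:

* **Magnitude** $m(r) = \exp(-r^2/\sigma^2)$, a Gaussian decay in the
  inward distance $r$ from the boundary, with $\sigma^2$ set to 10% of the
  cell area — larger cells generate force over a wider band.
* **Direction** $\mathbf{d}$: the cell outline is embedded as a signed
  distance level-set function $\phi$ (negative inside) and evolved for a
  short time $\tau$ under mean curvature flow (MCF),
  $\partial_t\phi = \kappa|\nabla\phi|$. MCF rounds off protrusions, so
  the inward gradient $-\nabla\phi(\cdot,\tau)/|\nabla\phi|$, sampled at
  grid points inside the *original* mask, yields a smooth inward field
  without the antiparallel-gradient artifacts that thin pseudopodia
  produce in the raw distance function.

Local deviations from this idealized field are handled by per-point hidden
corrections: a rotation $\theta_n$ and a scale $s_n$,
$\mathbf{f}_n = s_n R(\theta_n) \mathbf{f}_\mu(\mathbf{x}'_n)$, with an
uninformative prior on $\theta_n$ and a Laplace prior
$\exp(-\gamma\sum_n |s_n|)$ on the scales, which pushes unneeded
corrections to exactly zero, like a lasso.

## MAP estimation

With Gaussian observation noise (precision weight $\alpha$) and a Gaussian
prior around the corrected centers (weight $\beta$), the log posterior is

$$\log P(\mathbf{f}\mid \mathbf{u}_{obs}, \{\theta_n, s_n\}) =
-\tfrac{\alpha}{2}\|\mathbf{u}_{obs} - G\mathbf{f}\|^2
-\tfrac{\beta}{2}\|\mathbf{f} - F_\mu(\{\theta_n, s_n\})\|^2 + const.$$

`em_estimate()` maximizes the penalized objective (the expression above
minus $\gamma\sum|s_n|$) by coordinate ascent, which mirrors an EM scheme
with $\{\theta_n, s_n\}$ as hidden variables:

1. **Force step** — for fixed corrections the objective is quadratic and
   the maximizer is the solution of $(\alpha G^\top G + \beta I)\mathbf{f}
   = \alpha G^\top \mathbf{u}_{obs} + \beta F_\mu$, computed via a single
   Cholesky factorization reused across iterations and restarts.
2. **Correction step** — per point, the optimum is exact: $\theta_n$
   aligns the rotated prior center with the current force, and $s_n$ is
   the soft-thresholded ratio $|\mathbf{f}_n| / |\mathbf{f}_{\mu n}|$ with
   threshold $\gamma/(\beta\,|\mathbf{f}_{\mu n}|^2)$.

Both steps solve their subproblem exactly, so the objective is
non-decreasing (asserted at every iteration). The objective is non-concave
jointly, so five restarts are run — one from the unmodified prior
($s = 1, \theta = 0$), the rest from randomized corrections
($s \sim |N(1, 0.5^2)|$, $\theta \sim U(-\pi/4, \pi/4)$) — and the restart
with the highest final objective is kept. Convergence is declared at a
relative objective change below $10^{-6}$ (cap: 200 iterations).

### Hyperparameters and units

Defaults follow the model's reference settings: $\alpha = 1$,
$\beta = 0.1$ (the prior receives roughly 10% of the likelihood's weight),
$\gamma = 0.01$, $\sigma^2 = 0.1 \times$ cell area. Lengths are always
micrometers. Because the forward model depends on force only through
$f/E$, the force unit is tied to the Young's modulus; the package defaults
to $E = 1$, i.e. forces are expressed in units of $E$.

One parameter deserves emphasis: the **global prior scale** (`prior_scale`
in `btfe()`), the typical traction magnitude of the cell type in the same
force units. The Laplace penalty on $s_n$ is *not* invariant to the force
unit — its soft threshold scales as $1/|\mathbf{f}_\mu|^2$ — so a prior
center orders of magnitude below the true force scale thresholds every
correction to zero and silently degenerates the estimator to ridge
regression, while a grossly excessive scale lets the prior overwhelm the
data. We treat this scale as prior biological knowledge on the same
footing as the boundary itself (e.g. tens of Pa for neuronal growth
cones); the default 1 therefore means "forces measured in units of the
typical traction". The synthetic benchmark passes the generator's mean
force magnitude. Within a factor of ~2–3 of the true scale the results are
insensitive; data-driven estimation of this constant from the bead
displacements alone proved unreliable (displacement amplitude confounds
per-point magnitude with the number of active sites) and is deliberately
not attempted.

### MCF numerical choices

The level-set flow uses explicit central differences with
$dt = 0.2\,\text{px}^2$ (CFL-safe for the curvature term clamped at
$1/\text{px}$), with redistancing every 20 steps via the exact Euclidean
distance transform. Redistancing is *band-preserving*: $\phi$ is kept
unchanged within 2 px of the interface and only the far field is rebuilt,
because a fully binarized redistance pins the contour to the pixel grid
and stalls interface motion slower than half a pixel per redistance
interval. With this scheme a circle of radius 30 px evolved for
$\tau = 50\,\text{px}^2$ follows the analytic law
$R(\tau)^2 = R(0)^2 - 2\tau$ to better than 1%. The default $\tau$ shrinks
the circle-equivalent radius by 10% — enough to erase opposing gradients
in thin protrusions; estimation results are insensitive to its exact
value. Gradient directions are read from $\phi$ after a 2 px Gaussian
smoothing (`smooth_sigma`), which removes the faceting of the discrete
distance transform (up to 10° of spurious rotation on a perfect disk
otherwise, < 3° with smoothing). Grid points on the distance-function
skeleton, where the gradient vanishes, get a zero direction and are
flagged `degenerate`.

## Baselines

`tfm_baseline()` provides the standard regularized regressions on the
identical forward model: ridge
($\min \|\mathbf{u}-G\mathbf{f}\|^2 + \lambda\|\mathbf{f}\|^2$, solved on
the SVD so the whole $\lambda$ path costs one decomposition) and lasso
($\min \tfrac12\|\mathbf{u}-G\mathbf{f}\|^2 + \lambda\|\mathbf{f}\|_1$,
via glmnet without intercept or standardization; the penalty applies to
scalar components, with no group structure). $\lambda$ is chosen by 5-fold
cross-validation on a logarithmic grid ($10^{-4}$–$10^2$, 25 points);
folds are split **by bead**, so the x and y components of one bead never
straddle the train/test divide.

## The synthetic benchmark

Real traction fields are unknown, so accuracy is measured on synthetic
data built to emulate the experimental setting (`make_dataset()`):

1. a model cell boundary — geometric shapes (circle, square, triangle, X)
   or `blob`, a random Fourier perturbation of a circle standing in for
   irregular outlines of real motile cells (real outlines are not
   distributed with any imagery; the blob amplitude switches between
   complex, lobed cells at 0.35 and near-round cells at 0.08);
2. 20 traction points sampled inside the cell with the boundary-decay
   magnitude as placement weight, each pointing inward with Gaussian
   angular noise (sd 0.2 rad) and lognormal magnitude jitter (~±20%)
   around a mean magnitude of 10;
3. beads scattered uniformly at 0.4 or 1.6 beads/µm²;
4. forward displacements through the Boussinesq model, plus Gaussian
   observation noise of sd 0.1 µm.

The default raster is 256×256 px at 0.2 µm/px. The packaged benchmark
(`benchmark_suite()`) runs on a 96 px field — cells of roughly 100 µm²,
the size of a small motile cell such as a growth cone — which keeps a full
grid (5 cells × 2 densities × 10 bead replicates, three estimators at the
complex/low-density condition) in the ten-minute range on one core. With
the mean magnitude 10 and $E = 1$, bead displacements near the cell reach
0.5–1.5 µm against the 0.1 µm noise, the visibly-deformed regime of real
TFM recordings.

Accuracy indices (`roc_auc()`, `dtm()`, `dtmb()`), all restricted to grid
points inside the cell:

* **AUC** — generator force points are positives, all other interior grid
  points negatives; the estimated magnitude is swept through every
  threshold (Mann-Whitney convention, ties get half credit).
* **DTM** — mean relative magnitude error at the true force points; 0 is
  perfect, −1 means the estimate is essentially zero there.
* **DTMB** — mean estimated magnitude at the negative points divided by
  the mean true magnitude: how large the false-positive forces are.

## What passing tests do and do not show

The generator reproduces the *structure* of the benchmark — sparse inward
boundary-biased forces, uniform beads, Boussinesq displacements, Gaussian
localization noise — but not every property of real data: no bead
detection or tracking errors beyond isotropic Gaussian noise, no substrate
nonlinearity or finite thickness, no segmentation error in the boundary,
and synthetic blob outlines rather than real cell outlines. One visible
consequence: near-round *synthetic* cells at this desk scale remain fairly
identifiable (every estimator scores well above chance), whereas round
real-cell benchmarks are reported to hover near chance for ridge/lasso —
with forces individually resolvable at our signal-to-noise, rotational
ambiguity never fully develops. Conclusions about algorithm ordering on
complex boundaries transfer; absolute AUC levels on round cells should be
read as optimistic.

## Design choices that were genuinely open

* **Grid placement** — force points cover the full image bounding box;
  points are "inside" if their containing mask pixel is foreground.
* **Evaluation region** — interior grid points only, for every estimator,
  even though ridge/lasso estimate forces outside the cell too.
* **Restart distribution** — restart 0 from the unmodified prior, others
  jittered around it; the best final objective wins.
* **Bead placement guard** — beads landing within $10^{-6}$ µm of a force
  node are redrawn (the kernel diverges at zero offset); the estimator
  refuses such pairs with an explicit error.
* **Polygon input** — rasterized by an even-odd crossing-number test at
  pixel centers (no geometry dependency carries this operation here).
* **Tie-breaks in ROC** — midrank (trapezoid) convention, so AUC equals
  the Mann-Whitney statistic exactly.

## Known limitations

* The prior scale must be supplied when force units are not "typical
  traction = 1"; it is not estimated from data (see above).
* The flat half-space model excludes finite-thickness substrates, 3D
  traction components, and nonlinear elasticity.
* Cells with protrusions thinner than the force-grid spacing cannot be
  represented on the default 30×30 grid; use a denser grid (e.g. 60×60)
  at a quadratic cost in the force dimension.
* Posterior uncertainty (credible intervals) is not computed — only the
  MAP point estimate with its local corrections.
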