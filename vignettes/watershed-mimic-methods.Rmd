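---
title: "Methods: regularized watershed MIMIC models of tract FA and intelligence"
author: "wmimic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regularized watershed MIMIC models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(wmimic)
```

This vignette is the package's own account of its models, conventions and
numerical choices.  It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The model

The watershed MIMIC model has three layers.  Observed causes
`x` — the mean tract-based fractional anisotropy (mTBFA) of ten major
white-matter fascicles (ATR, CGC, CGH, CST, Fmj, Fmn, IFO, ILF, SLF, UNC)
plus age in years — predict two latent variables, fluid intelligence
(FI) and crystallized intelligence (CI), which produce the four WAIS-III
index scores (PO and PS load on FI; VC and WM on CI):

$$\eta = \Gamma x + \zeta,\qquad y = \Lambda\eta + \epsilon,$$

with $\zeta \sim (0, \Psi)$ full-covariance latent disturbances,
$\epsilon \sim (0, \Theta)$ diagonal indicator residuals, and exogenous
covariance $\Phi = \mathrm{Cov}(x)$.  The implied moments are

$$\Sigma_{yy} = \Lambda(\Gamma\Phi\Gamma' + \Psi)\Lambda' + \Theta,\qquad
  \Sigma_{yx} = \Lambda\Gamma\Phi,\qquad \Sigma_{xx} = \Phi.$$

Assumptions worth stating plainly: the measurement structure is
congeneric (each index reflects exactly one latent); causes act on the
indices only through the latents; all relations are linear; fitting is at
the covariance level on centered data (no mean structure); samples are
cross-sectional and complete after listwise deletion.

**Identification.** Default is the marker convention: the first listed
indicator of each latent has its loading fixed at 1 (PO for FI, VC for
CI), so each latent inherits its marker's scale; a unit-variance mode is
available.  **Exogenous block.** $\Phi$ is fixed at the sample covariance
of the predictors (conditional-on-x formulation).  Because the x-block is
then saturated, this is equivalent to estimating a free $\Phi$, and the
degrees of freedom count only the indicator–indicator and
indicator–predictor moments: $df = m(m+1)/2 + mq - n_{free}$.  This
reproduces the familiar CFA counts — df = 2 for the one-factor model of
the four indices, df = 1 for the two-correlated-factor model — and makes
the MIMIC df well-defined; whether the original analyses fixed or
estimated $\Phi$ is not documented, so MIMIC df may differ from the
original software's count.

## 2. Estimation and fit indices

`fit_ml()` minimizes the normal-theory discrepancy
$F_{ML} = \ln|\Sigma| + tr(S\Sigma^{-1}) - \ln|S| - p$ by BFGS with
analytic gradients on a transformed parameterization (variances on the
log scale, which keeps $\Theta > 0$ without constraints).  Conventions,
each exposed or documented because software differs:

* covariance divisor $N-1$, paired with the $\chi^2 = (N-1)F_{ML}$
  multiplier (an $N$ option exists);
* RMSEA $= \sqrt{\max(\chi^2-df,0)/(df\,(N-1))}$, 90% interval from the
  noncentral-$\chi^2$ coverage equations solved by root finding and
  truncated at zero;
* CFI against the independence baseline (indicators mutually uncorrelated
  and uncorrelated with the predictors, predictor block untouched);
* SRMR as the RMS of standardized residuals over the lower triangle
  including the diagonal, excluding the fixed x-block;
* BIC $= -2\log L + k \ln N$ with the full multivariate-normal
  log-likelihood and $k$ the free-parameter count;
* the Satorra–Bentler factor $c = tr(U\Gamma_N)/df$ from empirical
  fourth-order moments, with $\Delta$ computed analytically (tests check
  it against finite differences);
* indicator $R^2 = 1 - \Theta_{ii}/\hat\Sigma_{ii}$.

Reported $\chi^2$, RMSEA, CFI are the unscaled versions, with $c$ shown
separately.  A printed RMSEA in the motivating analysis is not
reproducible from its own $\chi^2$, df and N under either multiplier
convention (it is likely a robust variant); this package does not force
agreement.

**Convergence and degeneracies.** Gradient ∞-norm below 1e-7 (cap 500
iterations per BFGS round, with restarts), followed by a damped Newton
polish using a finite-difference Hessian of the analytic gradient so that
independently converged fits agree to ~1e-11.  The log parameterization
turns $\Theta_{ii}=0$ into a spurious stationary point; whenever a fitted
residual variance falls below 1% of the observed variance, the optimizer
restarts once from a start with that variance reset and keeps the better
discrepancy.  Solutions still at that boundary are flagged as Heywood
cases.  Non-convergence is reported in the result, never raised.

## 3. The elastic-net path and model selection

The penalized objective is

$$F_{ML}(S, \Sigma(\theta)) + \lambda \sum_{j \in pen}
  \bigl(\alpha|\theta_j| + (1-\alpha)\theta_j^2\bigr)$$

over the structural coefficients, all 22 of which are penalized by
default — including age, whose trajectories sit on the same penalty path
in the motivating analysis (an option exempts it).  Defaults: 35 equally
spaced $\lambda$ values from 0 to 0.35 and $\alpha = 0.5$.

**Optimization.** At each grid point (warm-started from the previous
one), the fitter alternates (a) BFGS over the smooth parameters plus the
currently nonzero penalized coefficients — on a fixed orthant the
$\ell_1$ term is linear, so this surrogate is smooth; coefficients that
cross zero are dropped back to the proximal step — with (b) FISTA
proximal-gradient sweeps over all penalized coordinates with backtracking
line search, until the joint stationarity residual (which accounts for
the subgradient at zeros) falls below 1e-7.  This yields exact zeros
without smoothing the penalty.  Converged penalized estimates below
1e-3 in absolute value are reported as exactly 0.

**Scale.** Penalties are not scale-invariant.  Coefficients are
penalized on the scale of standardized predictors and marker-identified
latents: the predictors (the "causes" of the MIMIC) are standardized
internally, the indicators keep their scale and the latents inherit their
marker's.  A fully standardized mode is available, and estimates are
reported on both the fitting and the original scale.

**Selection.** Each grid point is scored with
$BIC_{reg} = (N-1)F_{ML} + k\ln N$, where $k$ counts free non-penalized
parameters plus surviving penalized ones, and $F_{ML}$ is the discrepancy
of the sparsified model *refit by unpenalized ML with its zero pattern
held fixed* (a relaxed fit).  The original software's regularized-BIC
scale is not documented, so the definition was genuinely open; scoring
the refit rather than the shrunken estimates was chosen because it makes
the criterion a function of the proposed structure alone.  Evaluating
$F_{ML}$ at the penalized estimates instead couples the criterion to the
shrinkage: the $(N-1)$-scaled cost of shrinking strong true coefficients
grows quadratically in $\lambda$ and pushes the argmin to small
$\lambda$, where coefficients whose ML curvature is high (here
$\approx \sum_j \lambda_j^2/\theta_j \approx 6$ because the indicator
reliabilities are high) retain small spurious values above the
sparsification threshold.  With the relaxed-fit convention the selection
is consistent in the usual BIC sense; ties are broken towards the largest
$\lambda$ (the sparsest model).  Both the per-path estimates and the
refit are exposed, so users can score either way.

## 4. Tractography

`tensor_metrics()` eigen-decomposes each 3×3 symmetric tensor and returns
the ordered eigenvalues, the principal direction (sign convention:
largest-magnitude component nonnegative), the trace, and
$FA = \sqrt{\tfrac12}\sqrt{\sum_{i<j}(\lambda_i-\lambda_j)^2 /
\sum_i \lambda_i^2}$, defined as 0 for the all-zero tensor.

`fact_track()` is the FACT variant with voxel-wise constant directions
and exit-face stepping (no trilinear interpolation): from a seed voxel
center that passes the start criteria (FA ≥ 0.15 and trace ≤ 0.0016
mm²/s), the track follows the current voxel's principal eigenvector —
sign chosen to continue the previous heading — to the face it exits,
enters the neighboring voxel, and terminates on FA < 0.10, trace > 0.002,
a turn above 53.1°, or the grid boundary; propagation is bidirectional
and tracks visiting fewer than 5 voxels are discarded.  The turning angle
is measured between the directions followed in consecutive voxels;
whether the original toolbox interpolated directions or measured the
angle differently is not stated in its description, so this variant is
documented rather than claimed identical.

`brute_force_tracking()` seeds every qualifying voxel and de-duplicates
identical voxel sets.  `select_tract()` implements the multi-ROI rule
(visit every inclusion ROI, avoid every exclusion ROI); explicit
exclusion masks replace manual visual pruning — reproducibility over
fidelity.  `mean_tract_fa()` interprets "superposition" as the union of
visited voxels (unweighted); a visit-count-weighted option exists because
the source description does not specify.  `bilateral_average()` averages
hemispheres, warning when one side is missing.  Grids are 0-based
voxel-indexed internally with world coordinates via the affine; masks and
maps must share the grid — registration and resampling are out of scope,
as are DWI-to-tensor fitting and distortion correction.

## 5. Synthetic data: what it emulates and what it does not

`simulate_subject_table()` draws ten exchangeably correlated FA columns
(correlation 0.3, FA 0.45 ± 0.03 — plausible adult-tract values chosen
once as documented defaults, since the source reports no predictor
moments), age from a truncated normal (35.03 ± 10.27 on [18, 69], the
study's demographics), latents $\eta = \Gamma x + \zeta$ with unit
population variances, and indicators calibrated *analytically* so each
population $R^2$ hits its target exactly: with unit latent and indicator
variances, $\lambda_j = \sqrt{R^2_j}$ and $\theta_j = 1 - R^2_j$
(targets 0.856, 0.408, 0.756, 0.483), then rescaled to the WAIS index
means and SDs.  The default true structural support places standardized
effects of magnitude 0.3 on age→FI (+), age→CI (−), Fmn→CI (+), SLF→FI
(−) — the sign pattern of the selected edges in the motivating analysis;
the printed unstandardized coefficients there are too scale-ambiguous to
serve as simulation truth.  The latent disturbance correlation defaults
to 0.7, giving an implied FI–CI correlation near 0.45: fluid and
crystallized ability correlate strongly in adult samples, and a
near-orthogonal choice would make the two-indicator-per-factor
measurement model weakly identified in a way real index data are not.

What passing tests show: the estimator recovers parameters from data
generated by its own model family; selection recovers a known sparse
support at N = 1000; the tracker recovers constructed bundle FA.  What
they do not show: robustness to non-Gaussian FA distributions, crossing
fibers within a voxel, registration error, or misspecified measurement
structure — real data differ in all of these.

`make_dti_phantom()` builds prolate-tensor bundles (eigenvalues solved in
closed form from the requested FA and trace) along polyline paths in an
isotropic background that fails the start criteria, with ROI spheres at
25% and 75% arc length; overlapping bundles with incompatible
orientations are an error unless a crossing is requested.
`end_to_end_dataset()` closes the loop: per-subject phantoms whose
tracked mTBFA values replace the corresponding predictor columns.

## 6. Problem sizes and reproducibility

All generators are pure functions of (configuration, seed).  The shipped
experiments use: N = 1000 subjects and 20 replicates for support
recovery; N = 10⁵ for the calibration check; 50 replicates of N = 5000
for the Satorra–Bentler calibration (normal and multivariate-t₅ data —
the elliptical heavy-tailed family, where excess kurtosis provably
inflates the factor; independent-component heavy tails can leave the
residual directions of a factor model nearly unaffected); 500 replicates
of N = 500 for the χ² size check; and 20³–24³ voxel phantoms.  These
sizes were chosen so each check estimates its quantity with comfortable
Monte-Carlo margin.

## 7. Known limitations

* No mean structure, multi-group, longitudinal or categorical estimation;
  no FIML for missing data (listwise deletion only); no robust (scaled)
  RMSEA/CFI variants; no cross-validated λ selection.
* The regularized-BIC convention is this package's documented choice; the
  original software's numeric BIC scale is not reproduced.
* The FACT variant is voxel-constant by design; partial-volume boundary
  voxels are excluded by the stop criteria rather than modeled.
* Penalized inference provides no p values or confidence intervals; an
  edge's "importance" is its survival of selection.
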