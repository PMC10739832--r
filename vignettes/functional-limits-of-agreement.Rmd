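---
title: "Functional limits of agreement for curve-valued method comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional limits of agreement for curve-valued method comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floa)
```

## The problem

Method-comparison studies ask whether a new measurement method can replace an
established one.  For scalar measurements the standard answer is the
Bland–Altman 95% limits of agreement (LoA): the mean difference between
paired measurements plus or minus twice its standard deviation.  In human
movement analysis, however, the measurement is a *curve* — a joint angle as a
function of normalized movement time, conventionally resampled to 101 frames
covering 0–100% of the cycle — and study designs are hierarchical: each of
several subjects performs several replicate movements in each of several
sessions, captured simultaneously by both methods (for example a marker-based
and a markerless motion-capture system).

`floa` extends the limits-of-agreement idea to this setting.  The frame-wise
difference curves

$$ d_{ijk}(t) = y_{m_1 ijk}(t) - y_{m_2 ijk}(t), \qquad
   i = \text{subject},\; j = \text{session},\; k = \text{replicate}, $$

are modelled with a three-level nonparametric linear mixed-effects model

$$ \mathbf d_{ijk} = \mathbf X \boldsymbol\beta
   + \mathbf Z\, \mathbf b_{i}
   + \mathbf Z\, \mathbf b_{ij}
   + \mathbf Z\, \mathbf b_{ijk}
   + \boldsymbol\varepsilon_{ijk}, $$

with
$\mathbf b_i \sim N(\mathbf 0, \boldsymbol\Psi_1)$ (subject),
$\mathbf b_{ij} \sim N(\mathbf 0, \boldsymbol\Psi_2)$ (session within
subject), $\mathbf b_{ijk} \sim N(\mathbf 0, \boldsymbol\Psi_3)$ (replicate),
and $\boldsymbol\varepsilon_{ijk} \sim N(\mathbf 0, \sigma^2 \mathbf C)$,
where $\mathbf C$ is a stationary ARMA(p, q) correlation matrix on the frame
grid.  $\mathbf X$ and $\mathbf Z$ are basis matrices evaluated on the grid,
so both the bias curve and the smooth random deviations are nonparametric.

The 95% *functional* limits of agreement are the pointwise band

$$ \hat{\boldsymbol\mu}_d \pm 2 \sqrt{\operatorname{diag}
   (\hat{\boldsymbol\Lambda}_d)}, \qquad
   \hat{\boldsymbol\mu}_d = \mathbf X \hat{\boldsymbol\beta}, \qquad
   \hat{\boldsymbol\Lambda}_d =
   \mathbf Z \hat{\boldsymbol\Psi}_1 \mathbf Z' +
   \mathbf Z \hat{\boldsymbol\Psi}_2 \mathbf Z' +
   \mathbf Z \hat{\boldsymbol\Psi}_3 \mathbf Z' + \hat\sigma^2 \mathbf C . $$

$\boldsymbol\Lambda_d$ here is the covariance of a *single new* difference
curve: the band describes where a fresh paired measurement's difference is
expected to fall, so the cross-curve covariance terms that couple repeated
measurements of one subject do not enter its diagonal.  The multiplier is 2
(not 1.96), the convention inherited from classical limits of agreement; it
is configurable.  The band is interpreted pointwise — at each frame it aims
to contain about 95% of difference values — not as a simultaneous band for
whole curves, which would be wider.

## Choosing the model components

**Fixed-effects basis.**  The bias curve is expanded in cubic B-splines with
equally spaced interior knots and clamped boundary knots (multiplicity
degree + 1 at the grid endpoints — the standard regression-spline convention
on a closed interval).  Under the default no-intercept dialect a system with
$k$ interior knots has $k + 3$ basis functions (9 knots give 12); the
with-intercept dialect adds one function and makes rows sum to one.  Since
angle curves are baselined to range of motion (initial angle subtracted),
difference curves start at zero and a basis vanishing at the left boundary
is appropriate; for non-baselined data use `intercept = TRUE`.

**Knot selection.**  Rather than refitting the full mixed model under many
knot sequences and comparing information criteria, `select_knots()` fits an
ordinary regression spline to every individual difference curve and picks
the smallest candidate count of interior knots for which *all* curves reach
adjusted $R^2 \ge 0.95$ ("all" is a strict minimum over curves; both the
threshold and the candidate set {0, 1, 3, 9, 19, 32} are configurable).
When no candidate qualifies, the largest is returned with a warning rather
than an error, so pipelines proceed on deliberately rough data.

**Random-effects basis and covariance.**  The safe choice is the same
B-spline system as the fixed effects with an *unstructured* covariance at
every level — but an unstructured $q \times q$ covariance needs
$q(q+1)/2$ parameters, e.g. 78 at $q = 12$ and 234 over three levels, which
is expensive.  The fast alternative follows the Karhunen–Loève idea: the
sample covariance $\mathbf S$ of the (mean-centered, pooled) difference
curves is eigendecomposed, $\mathbf S = \mathbf Q \boldsymbol\Lambda
\mathbf Q'$, and the leading eigenvectors explaining at least 99% of the
variance form an orthonormal random-effects basis on which the coefficient
covariance can be taken *diagonal*, since coefficients of a process on the
eigenfunctions of its covariance are uncorrelated.  `eigen_basis()`
implements this; the variance fraction is configurable, sample-mean
centering is the default (the theorem concerns a zero-mean process and the
fixed-effects mean is unknown before the fit, so the sample mean curve is
the practical stand-in), and eigenvalues below $10^{-10} \lambda_{\max}$ are
treated as zero.  One eigenbasis is computed per scenario and shared by all
three levels.

**Error structure.**  Within-curve errors of time-normalized kinematic
measurements are serially correlated.  The supported correlation families
are iid, AR(1), CAR(1) (geometric decay with a positive parameter), and
ARMA(p, q); the pipeline default is a fixed ARMA(2,1), which in our
experience (and in the motion-capture literature this package grew from)
removes residual autocorrelation across scenarios.  An automated
alternative (`error = list(select = "auto")`) fits a small family list and
ranks by whitened-ACF bound exceedances, then BIC — an explicit rule in
place of choosing by eye from ACF plots.

## REML estimation

Only restricted maximum likelihood is used: it accounts for the degrees of
freedom spent on the fixed effects, which matters with 54 curves and a
12-dimensional bias basis.  The implementation profiles out both
$\boldsymbol\beta$ (by generalized least squares) and $\sigma^2$, carrying
the level covariances relative to $\sigma^2$, so the optimizer only sees the
unconstrained variance-structure parameters:

* unstructured $\boldsymbol\Psi$: log-Cholesky (log diagonal, free
  sub-diagonal);
* diagonal $\boldsymbol\Psi$: log standard deviations;
* ARMA coefficients: partial autocorrelations through $\tanh$, mapped to
  coefficients by the Levinson–Durbin step-up recursion (the MA polynomial
  uses the dual map), which enforces stationarity and invertibility at every
  iterate; CAR(1) uses a logistic map to (0, 1).

Subjects are independent, so the likelihood factorizes over subject blocks.
For *balanced* designs (every subject has the complete session-by-replicate
crossing, and all curves share the bases — the common case) an orthogonal
contrast transform across each subject's curves block-diagonalizes the
subject covariance into three frame-sized matrices,

$$ \mathbf M_3 = \mathbf C + \mathbf Z \mathbf D_3 \mathbf Z', \quad
   \mathbf M_2 = \mathbf M_3 + K\, \mathbf Z \mathbf D_2 \mathbf Z', \quad
   \mathbf M_1 = \mathbf M_2 + JK\, \mathbf Z \mathbf D_1 \mathbf Z', $$

associated with within-session replicate contrasts, session contrasts, and
the subject mean curve respectively.  One likelihood evaluation then costs
three Cholesky factorizations of frame-sized matrices instead of one
factorization of each stacked subject block, and because the fixed design is
shared by all of a subject's curves, only the mean block carries
$\boldsymbol\beta$.  Unbalanced data fall back to dense per-subject blocks;
the two paths agree to near machine precision and the test suite checks
this.  (The balanced decomposition replaces the low-rank/banded matrix
identities one might otherwise use: it is exact, simpler, and faster here.)

Optimization uses `nlminb` (a quasi-Newton method with bound-free
parameters) from moment-based starting values — pooled residual variance of
per-curve spline fits for $\sigma^2$, between-curve coefficient variances
split across levels for the $\boldsymbol\Psi$ diagonals — plus one perturbed
start by default (`n_starts = 2`, configurable); convergence follows
`nlminb`'s defaults with at most 500 iterations, and non-convergence returns
the best point found with a warning flag rather than an error.  A singular
candidate covariance yields a penalized objective value, not a crash.  Fits
are deterministic given the data and configuration.  BLUPs are the standard
conditional means $\hat{\boldsymbol\Psi}_l \mathbf Z_l' \mathbf V^{-1}
(\mathbf d - \mathbf X \hat{\boldsymbol\beta})$, computed densely once at
the optimum.

On shared-capability models (random intercepts, iid errors, and also
single-level ARMA models) the criterion and the full fit agree with
`nlme::lme` to at least six decimals; the test suite pins this down together
with closed-form ANOVA estimators on balanced one-way designs.

## Diagnostics

`residual_acf()` whitens each subject's stacked marginal residuals with the
Cholesky factor of the *full* fitted covariance and averages the residual
ACF over curves, with $\pm 2/\sqrt N$ reference bounds.  Under a correct
model the whitened innovations are exactly white; whitening conditional
(BLUP-subtracted) residuals by the error covariance alone is also offered,
but BLUP shrinkage leaves a systematic autocorrelation of order $q/T$ even
under the true model, so the marginal form is the default and the one used
to compare error structures.

`residual_vs_average()` is the functional analogue of the Bland–Altman
assumption check: each residual is plotted against the average of the two
methods' values at that (curve, frame), ignoring the time index.  A trend
indicates bias or variance structure the model missed; a straight-line slope
with its standard error is attached as a plot-free summary.

`empirical_coverage()` reports the fraction of difference values inside the
band — about 0.954 for a correctly calibrated $\pm 2$ SD band on Gaussian
differences.

## The synthetic study generator

The package's generator (`sim_config()`, `simulate_differences()`,
`simulate_paired_methods()`) draws data from exactly the model above, with
the hierarchical dimensions of the motivating motion-capture study: 9
subjects, 2 sessions, 3 replicates, two methods, 101 frames — 108 measured
curves and 54 difference curves per scenario.  Its defaults define the
study conditions used throughout the tests:

* **Truth basis.**  An *orthonormalized* cubic B-spline system with 3
  interior knots (6 functions).  Equal diagonal level variances on an
  orthonormal basis make each level covariance a scalar multiple of the
  projection onto the spline space, so the generating model is invariant to
  within-span rotations — the fitted eigenbasis may be any rotation of the
  truth span without mis-specifying the diagonal covariance, which keeps
  recovery experiments well-posed.  The dimension is deliberately moderate:
  a basis estimated from the study's own 54 curves absorbs roughly
  $q(T-q)/(nT)$ of the error variance through sample-eigenvector overfit
  (about 9% at $q = 6$, but over 20% at $q = 12$), so a higher-dimensional
  smooth truth would leave the error variance unidentifiable at this sample
  size no matter the error process.
* **Bias.**  A plateau of 20 degrees over frames 25–75 with smoothstep
  shoulders ("hipabd"), projected onto the truth basis so the generating
  mean lies exactly in a correctly sized fixed-effects span.  The magnitude
  echoes the mid-movement hip-abduction bias scale reported for
  markerless-versus-marker-based systems; it is an emulation, not a
  reproduction.  A coherent, non-representable mean component is *not*
  innocuous: it drives REML (in this implementation and in `nlme` alike)
  into a degenerate near-unit-root ARMA solution that acts as a free
  smoother.
* **Level variances.**  Diagonal values (6, 6, 24) degrees² give pointwise
  smooth deviation SDs of roughly 0.6 / 0.6 / 1.2 degrees at the subject /
  session / replicate levels — trial-to-trial variation dominating
  between-subject and between-session effects, and subject-level spread
  small enough that nine subjects afford bias-curve estimation to a few
  tenths of a degree.
* **Error.**  ARMA(2,1) with $\phi = (0.7, -0.49)$, $\theta = 0.2$ and
  marginal variance $\sigma^2 = 0.015$ (SD 0.12 degrees).  The complex AR
  roots put the spectral peak near a 6-frame period, *between* the smooth
  spline band and white noise: a strongly low-frequency error is confounded
  with the smooth random effects, while a near-white ARMA(2,1) suffers
  AR/MA root cancellation and leaves $(\phi, \theta, \sigma^2)$ on an
  identifiability ridge.  The noise share is under 1% of the total curve
  variance, the regime (implied by the published study's smooth variation of
  several degrees next to sub-degree sensor noise) in which the
  99%-variance eigenbasis truncation retains exactly the smooth
  between-curve variation.  ARMA paths are simulated by filtering with a
  500-step burn-in and scaled so the *marginal* variance equals
  $\sigma^2$ (the correlation matrix has unit diagonal).

What the generator does **not** emulate: biomechanically realistic
joint-angle waveforms, soft-tissue artefacts, heteroscedastic or
movement-phase-dependent noise, outlying trials, and missing frames.
Passing tests on this generator therefore demonstrate that the estimation
machinery recovers the model it claims to fit under realistic sizes and
noise ratios — not that any particular pair of capture systems agrees.

## Problem sizes used by the test and acceptance suites

Unit tests run on reduced designs (4 subjects, 31 frames) where closed
forms and brute-force oracles are exact or cheap.  The statistical
acceptance checks run at study scale: 20 simulated studies for parameter
recovery and band calibration (each fit takes a few seconds via the
balanced fast path), $10^5$ simulated curves for the single-curve variance
oracle, and a $10^6$-step path for the ARMA autocorrelation oracle.

## Known limitations

* The band is pointwise; simultaneous coverage of whole curves is smaller
  and is not estimated.
* Heteroscedastic variance functions over frames (the V matrix of the
  general error decomposition) are fixed to a constant; the hook exists in
  the error specification but no variance function is implemented.
* Only nested subject/session/replicate designs are supported — no crossed
  random effects, and frame-level missingness within a curve is rejected
  rather than imputed (whole missing curves are handled, via the dense
  path).
* Estimation is REML-only by design; ML and information-criterion-based
  structure search across non-nested fixed effects are out of scope.
* With very few groups at a level (e.g. two sessions per subject), that
  level's variance is weakly identified; the fitter warns rather than
  refuses.
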