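---
title: "Surface-based template ICA for individual neonatal network maps: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface-based template ICA: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(surftica)
```

# The problem

Resting-state networks (RSNs) are hard to estimate in individual
neonates: scans are short, motion is idiosyncratic, and the
signal-to-noise ratio is low. Group ICA averages away individual
topography; plain dual regression transfers group maps to a subject but
inherits all of the single-subject noise. `surftica` implements the
middle road: a hierarchical Bayesian ("template ICA") model in which a
subject's spatial maps are Gaussian deviations around an empirical
population template, so that short scans borrow strength from the
population while individual differences remain expressible.

# The model

For subject $i$, the dimensionally reduced BOLD data at vertex $v$ is

$$y_i(v) = A_i\, s_i(v) + e_i(v), \qquad e_i(v) \sim N(0, \nu^2 I),$$

where $A_i$ is the $T' \times Q$ mixing matrix for $Q$ networks and
$s_i(v)$ the vector of subject-level spatial-map values. The hierarchy
is

$$s_i(v) = \mu_0(v) + \delta_i(v), \qquad
  \delta_i(v) \sim N\!\big(0, \mathrm{diag}(\sigma^2_{0,1}(v), \dots,
  \sigma^2_{0,Q}(v))\big),$$

with population mean $\mu_0$ and between-subject variances
$\sigma^2_{0,q}$ estimated empirically (below). Because prior and
likelihood are Gaussian, the vertex-wise posterior of $s_i(v)$ is
Gaussian with closed-form mean and covariance
(`posterior_update()`); the mixing matrix and noise variance are
estimated by EM (`em_fit()`), alternating the posterior E-step with the
least-squares M-step

$$A \leftarrow \Big(\sum_v y_v\, \mathrm{E}[s_v]^\top\Big)
              \Big(\sum_v \mathrm{E}[s_v s_v^\top]\Big)^{-1}, \qquad
  \nu^2 \leftarrow \frac{1}{T'V}\sum_v \mathrm{E}\|y_v - A s_v\|^2.$$

The observed-data log-likelihood is recorded every iteration; its
monotone ascent is asserted by the tests as an internal correctness
check of the update derivation (the updates themselves are the standard
Gaussian complete-data maximizers, derived here rather than copied from
a reference).

Noise is modelled as spherical ($\nu^2 I$) on the reduced data. A
general noise covariance would be unidentifiable at $T' = Q$ retained
dimensions, and a single residual variance is the minimal model
consistent with initializing $\nu^2$ from the mean discarded eigenvalue
of the SVD reduction (`reduce_dimension()`).

# Empirical population priors

Template estimation (`estimate_template()`) uses pseudo test-retest
dual regression: each template subject's run is split into two
contiguous halves (`split_pseudo_sessions()`; contiguity preserves
autocorrelation within a half), each half is dual-regressed against the
group maps, and for each vertex and IC

* the population mean is the average of all $2N$ maps,
* the total variance is the session-average of the between-subject
  variances,
* the within-subject (noise) variance is half the variance of the
  session difference,
* the between-subject variance is their difference (the identity
  $\sigma^2_{tot} = \sigma^2_0 + \sigma^2_{noise}$ holds exactly before
  clamping; algebraically the raw between-subject estimate equals the
  cross-session sample covariance).

All variances use the unbiased $N-1$ estimator. Dual-regression stage-2
coefficients are kept in raw units (timecourses demeaned, not
variance-normalized) so the template and the Bayesian model share a
scale. Template subjects are excluded from all further analysis; the
pipeline enforces disjointness before any computation.

**Negative variance estimates and the floor.** Under the null (no true
between-subject variance) the raw estimate is symmetric around zero, so
roughly half of such vertices come out negative and are clamped.
`estimate_template()` defaults to a nominal floor
($10^{-6} \times$ median total variance), which keeps the prior proper.
For end-to-end runs, however, a near-zero floor is a trap: at clamped
vertices the prior becomes almost degenerate, every subject's posterior
is pinned to the template with vanishing posterior SD, and t-statistics
grow without bound — the engagement maps then reflect the template, not
the subject. `run_pipeline()` therefore floors the between-subject
variance at `variance_floor_frac` (default 5%) of the median total
variance, encoding "variance too small for this template cohort to
resolve" as a small but honest uncertainty. The fraction is
configurable; an explicit `variance_floor` overrides it.

# Preprocessing

* **DVARS** (`compute_dvars()`): root-mean-squared frame-to-frame
  signal change over included vertices, `dvars[1] = 0` by convention.
  The input is used as provided (no intensity normalization); the
  convention is documented because DVARS magnitudes are
  scale-dependent.
* **Flagging** (`flag_outliers()`): a frame is an outlier when DVARS
  exceeds Q3 + 1.5 IQR of the run, quartiles with linear interpolation
  (type 7) — the most common default, stated for reproducibility.
* **Block selection** (`select_block()`): the contiguous window with
  the fewest flags (earliest on ties, verified against brute-force
  enumeration); the subject is excluded when strictly more than
  `floor(0.10 * block)` frames in the chosen window are flagged
  (e.g. more than 160 of 1600).
* **Smoothing** (`smooth_surface()`): geodesic Gaussian smoothing
  approximated by iterated edge-weighted diffusion. A symmetric
  doubly-stochastic one-step operator (Sinkhorn-balanced Gaussian edge
  weights) makes constants fixed points and conserves the vertex sum
  exactly; the number of lazy steps is chosen so the accumulated
  per-axis displacement variance equals
  $\sigma^2 = \mathrm{FWHM}^2 / (8 \ln 2)$, and the CLT drives the
  iterated kernel to the heat kernel. Accuracy is property-tested
  against a planar Gaussian on a fine flat lattice (correlation
  > 0.98). Exact geodesic-distance kernels would be disproportionate at
  these mesh scales; the diffusion route is standard for surface fMRI.

# Subject-level maps and cohort statistics

t-maps divide posterior mean by posterior SD. Engagement masks apply a
one-sided test of engagement $> 0$ at Bonferroni level
$\alpha / V_{\mathrm{incl}}$ per IC (the correction is per IC because
each IC's map pair is tested as a family; correcting additionally over
ICs is available as an option, as is a two-sided test). The degrees of
freedom are configurable; the pipeline uses retained frames minus $Q$.
(A "reduced timepoints minus sources" rule would be identically zero
here since the reduction keeps exactly $Q$ dimensions, so the
pre-reduction temporal degrees of freedom are the sensible choice; a
normal approximation via `df = Inf` is also supported.)

Winner-takes-all parcellation assigns each included vertex the signal
IC with the highest t (ties to the lowest index, a documented
deterministic rule; nuisance ICs never win). The frequency map reports,
per vertex, the modal label across subjects and the fraction of
subjects carrying it (unassigned vertices count toward the mode only
when unanimous).

Connectivity strength is the vertex-area-weighted mean t inside the
engagement mask. The age-trend test residualizes strength and age on
an intercept plus covariates (sex, motion) by least squares and
computes Spearman's rho between the residuals, with two-sided p-values
from the AS 89 evaluation of the Spearman null distribution as
implemented in R's `stats::cor.test` (exact for small tie-free samples,
Edgeworth series otherwise; with ties, midranks and the t-approximation
are used, since AS 89 assumes no ties). Residualization is one of
several reasonable partialing schemes; it is rank-preserving for the
monotone alternatives of interest and reduces to plain Spearman with no
covariates. No correction across networks is applied — each network's
trend is reported at its own level.

# The synthetic cohort generator

`make_cohort()` runs the generative model forward, and its defaults are
the study conditions of every validation result in this package:

* **Group maps**: $Q$ Gaussian bumps of geodesic distance on an
  icosphere atlas, centres by farthest-point sampling (disjoint peaks,
  identifiable toy topography). A polar cap (5% of vertices) is
  excluded, standing in for the medial wall.
* **Subject maps**: group maps plus vertex-wise Gaussian deviations
  with network-specific variance
  $\sigma^2_{dev}\,c_q^2\,(0.25 + g_q(v))$, $c_q \in [0.75, 1.25]$ —
  variance is larger inside a network's own territory and differs
  between networks.
* **Timecourses**: Gaussian white noise convolved with a Gaussian
  window (autocorrelated but hemodynamics-free), variance-normalized.
* **Age effect**: the network amplitude $1 + \beta\,z(\mathrm{age})$
  multiplies the IC's mixing column. This matters: a scalar placed on
  the spatial map is re-absorbed by the mixing matrix during estimation
  (the scale ambiguity of $y = A s$ with the prior anchoring $s$ at
  $\mu_0$), leaving t-maps age-invariant. On the mixing side the
  amplitude raises the network's share of data variance relative to the
  fixed noise floor — an SNR effect, which is also the physiologically
  sensible reading of a maturational engagement increase — and reaches
  the t-statistics through the posterior SD.
* **Motion spikes**: a transient additive offset (default
  $10 \times$ noise SD, guaranteeing DVARS detectability) on listed
  frames. A transient offset at frame $k$ corrupts the temporal
  derivative at $k$ and $k+1$; the generator records that affected set,
  which is the ground truth against which flagging
  sensitivity/specificity is judged.

Defaults used across the validation suite: noise SD 3 (per-frame
network signal well below the noise floor, i.e. "moderate noise" for a
single network whose map peaks at 1 with unit-variance timecourses),
deviation SD 0.3, ages uniform on 37–45 weeks PMA, TR 0.392 s (a fast
multiband neonatal acquisition), $\beta = 0.5$ where an age effect is
wanted.

What the generator deliberately omits: hemodynamic response shapes,
physiological (cardiac/respiratory) noise, spatially autocorrelated
noise, and non-Gaussian artifacts. Passing tests therefore demonstrate
correctness of the estimation machinery under the model's own
assumptions — not robustness to the full noise structure of real
neonatal fMRI, where upstream cleanup (e.g. ICA-based denoising) is
assumed to have Gaussianized the residuals.

# Problem sizes and numerical choices

Validation runs use icosphere atlases of 162–2562 vertices, cohorts of
40–95 subjects, 100–300 frames and 3–8 networks; the end-to-end
demonstration fits 52 subjects (12 template + 40 analysis) at 2562
vertices. These sizes are chosen so every property — template recovery,
posterior calibration, censoring exactness, age-trend power and type-I
control — is exercised at cohort scale while the whole suite runs on a
laptop. EM uses `tol = 1e-4` relative parameter change and
`max_iter = 100`, single-start, initialized from dual regression
against the template mean (mixing) and the SVD residual variance
(noise); non-convergence warns and returns the current posterior
flagged `converged = FALSE`. Posterior covariance solves use Cholesky
factorization of the $Q \times Q$ precision; the E-step loops over
vertices in compiled code. Degenerate cases are defined behavior:
zero-variance vertices in tSNR are flagged invalid rather than
infinite, empty engagement masks yield missing strengths (dropped from
trend tests with a warning), rank-deficient group maps name their
collinear columns, and disconnected smoothing domains warn and smooth
per component.

# Known limitations

* The spherical noise model ignores temporal autocorrelation within the
  reduced data; standard errors inherit this approximation.
* The prior is vertex-independent (no spatial regularization of the
  deviations); posterior maps are as smooth as data and template make
  them.
* Amplitude (scale) differences between subjects are attributed to the
  mixing matrix by construction; spatial maps encode shape, not gain.
* The engagement degrees of freedom treat reduced dimensions as fixed
  regressors; a fully Bayesian treatment of the t-threshold is out of
  scope.
* With small template cohorts the between-subject variance is noisy and
  often clamped; the pipeline's variance floor is a pragmatic
  regularization, not an estimate.
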