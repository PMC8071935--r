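---
title: "IVIM model fitting and tumor-grade discrimination: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{IVIM model fitting and tumor-grade discrimination: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivimgrade)
```

## The signal model and its assumptions

Intravoxel incoherent motion (IVIM) imaging attributes diffusion-weighted
signal decay to two exponential pools:

$$\frac{S_b}{S_0} = f\,e^{-b D^*} + (1-f)\,e^{-b D},$$

where $D$ (mm²/s) is tissue water diffusion, $D^*$ (mm²/s) is the much
faster pseudo-diffusion of blood in randomly oriented capillaries, and
$f$ is the perfusion fraction of the $b=0$ signal. The model assumes
exactly two pools, no exchange, no T2/TE dependence of the compartment
weights, and magnitude signals normalized by the unweighted acquisition.
`ivimgrade` stores $D$ and $D^*$ in mm²/s internally and converts to the
conventional display units ($10^{-3}$ and $10^{-2}$ mm²/s) only in
reporting tables — one canonical unit avoids scale bugs.

The default acquisition design (`default_scheme()`) uses ten b values
(0–1000 s/mm², seven of them at or below 200) with per-b excitation
counts (2,2,2,2,2,2,2,4,6,8): a typical 3T esophageal protocol in which
averaging is increased where diffusion weighting suppresses signal most.

## The two estimators

**Segmented (mono-exponential) fitting** exploits the separation of decay
scales. Where $bD^* \gg 1$ the perfusion term is gone and

$$\frac{S_b}{S_0} \approx (1-f)\,e^{-bD},$$

so: (1) ordinary least squares of $\log(S_b/S_0)$ on $b$ over the high-b
set ($b > 200$ s/mm² by default) gives $D = -\text{slope}$ and the
extrapolated intercept at $b=0$; (2) $f = 1 - \text{intercept}$; (3) with
$D$ and $f$ fixed, $D^*$ is the one-dimensional bounded least-squares
minimizer of the full model's squared residuals in signal space. The
threshold b value itself (200) belongs to the *low* set: the high set is
defined by strict inequality, which keeps four high-b points in the
default scheme.

**Full (bi-exponential) fitting** estimates $(D, D^*, f)$ simultaneously
by bounded Levenberg–Marquardt nonlinear least squares
(`minpack.lm::nls.lm`) over all b values. Although parts of the
literature describe hybrid schemes, we implement the standard meaning of
a full fit — one joint three-parameter optimization — and use the
segmented estimates only as the starting point (a `fixed-init` mid-bounds
start is available; both reach the same optimum on identifiable curves,
which the test suite asserts).

### Numerical choices

- Residuals are minimized in linear signal space (not log space) for both
  nonlinear steps, matching the model as written in $S_b/S_0$ form.
- Bounds: $D \in [10^{-5}, 5\times10^{-3}]$,
  $D^* \in [10^{-3}, 0.5]$ mm²/s, $f \in [0,1]$ — bracketing published
  esophageal-tumor values by several standard deviations. Boundary hits
  are flagged in the fit diagnostics, never silently accepted.
- Convergence: relative residual tolerance $10^{-10}$, at most 500
  iterations; curves have ≤ 10 points so cost is negligible.
- An extrapolated intercept above 1 is clamped to 1 (implying $f=0$) and
  flagged. An estimated $f \le 0.005$ leaves $D^*$ unidentifiable (the
  perfusion term carries no signal); $D^*$ is then reported at its lower
  bound with a `dstar_not_identifiable` flag rather than an arbitrary
  interior value.
- Label switching: the bi-exponential model is symmetric under swapping
  $(D, D^*)$ and complementing $f$. If the optimizer returns
  $D^* \le D$, the canonical ordering is restored when doing so leaves
  the residual unchanged; otherwise a `dstar_below_D` warning flag
  stands.
- The $D^*$ step of the segmented fit uses all b values by default; a
  config switch (`dstar_b_range = "low"`) restricts it to the low-b set,
  since workstation implementations differ on this point.

### Where the segmented estimator's accuracy claims hold

The segmented fit is exact only in the asymptotic regime where the
perfusion exponential has decayed *in absolute terms* above the
threshold, i.e. $b_{\min,\text{high}} \cdot D^* \gg 1$. A large ratio
$D^*/D$ alone is not sufficient: with $D^* = 5\times10^{-3}$ mm²/s the
perfusion term still contributes $e^{-400 D^*} \approx 0.14$ of its
weight at $b = 400$, and noise-free segmented errors reach several
percent. The test suite therefore asserts the documented error bounds
(≤ 2% on $D$ and $f$, ≤ 5% on $D^*$) on the regime
$D^* \ge \max(10\,D,\ 1.2\times10^{-2}\ \text{mm}^2/\text{s})$, where the
premise of the asymptote holds; the published esophageal group means all
lie inside it.

## The synthetic-cohort generator

`simulate_cohort()` emulates the statistical structure of a three-grade
esophageal study: groups WD (well-differentiated, n = 20), MD (moderately,
n = 20) and PD (poorly, n = 14); per-grade parameter distributions whose
means and SDs are the published segmented-model group summaries (a config
switch selects the full-fit summaries instead); the ten-b-value scheme
with its NEX vector; Rician magnitude noise; and the ROI protocol (three
ROIs on each of three tumor sections, 9 per patient).

Generation of one patient: draw one truth $(D, D^*, f)$ from independent
truncated normals — $D$ on $(0,\infty)$, $D^*$ on $(D,\infty)$ so the
perfusion pool is always the faster one, $f$ on $(0.01, 0.9)$ — then for
each ROI average `voxels_per_roi` noisy voxel curves into one ROI curve,
renormalize it by its $b=0$ value, fit it with both estimators, and
average the fitted *parameters* across ROIs. Averaging signals within an
ROI but parameters across ROIs mirrors the measure-then-average protocol
of workstation-based studies.

Noise: each excitation observes $\sqrt{(A+g_1)^2+g_2^2}$ with
$g_1,g_2 \sim N(0,\sigma)$ — Rician magnitude noise, reducing to Rayleigh
at zero signal — and the scanner averages the per-b excitations. $\sigma$
is constant across b (thermal noise); NEX averaging is the only
b-dependent noise reduction. The default SNR at $b=0$ per excitation is
50, a typical figure for 3T body diffusion imaging; source studies rarely
state SNR, so it is a config parameter (`snr0`), set once and not tuned.
Parameters are drawn independently within a patient because only marginal
group means and SDs are published; no covariance is recoverable.

**What the generator does not emulate:** spatial structure (it is a
curve-level, not image-level, phantom), motion and susceptibility
artifacts, esophageal peristalsis, inter-reader ROI variability (ROI
replication is the stand-in), and any truth-level correlation between
$D$, $D^*$ and $f$. Consequently, passing tests show that the *analysis
chain* behaves correctly under the stated statistical structure — not
that real esophageal data satisfy that structure. Two visible artifacts
of the simplifications: truncating $D^*$ at $D$ slightly shrinks and
shifts the $D^*$ distributions relative to their nominal moments, and
simulated $D^*$ separates grades more cleanly than the in-vivo
high-variance behavior of $D^*$ suggests.

## Grading statistics

For each of the six parameter–model combinations the comparison follows
the conventional decision rule: Shapiro–Wilk on each grade group at
$\alpha = 0.05$; if all three groups pass, one-way equal-variance ANOVA
with Fisher's least-significant-difference (LSD) post hoc — unadjusted
pairwise t tests on the pooled within-group mean square error, which is
what LSD means — otherwise Kruskal–Wallis with no post hoc. The gate is
applied per group per parameter (the standard reading when granularity is
unstated), routes exclusively to one path, and no multiplicity correction
is applied across the six parameters, matching common practice in this
literature (a Holm option exists for users who want it).

Spearman correlation relates each parameter to grade coded
PD = 1 < MD = 2 < WD = 3. This coding is forced by the reported sign
structure of the field: $D$ is largest in well-differentiated tumors
(positive correlation with differentiation), $f$ largest in
poorly-differentiated ones (negative). The coding is configurable;
flipping it negates $\rho$.

ROC analysis is pairwise between grade groups with the
less-differentiated group as the positive class, so $f$ discriminates
with direction "greater is positive" and $D$ with "lesser is positive".
AUC is the Mann–Whitney pair-ordering probability (identical to the
trapezoidal area under the empirical ROC curve — asserted as a
two-implementation identity in the tests, and cross-checked against
`pROC`). Cutoffs maximize Youden's $J = \text{sens} + \text{spec} - 1$
over all midpoints of adjacent sorted values, ties broken toward higher
specificity then lower cutoff; published sensitivity/specificity pairs in
this literature are consistent with Youden-style optimization even where
the criterion is unnamed. AUC interpretation bands: $[0.5, 0.7)$ low,
$[0.7, 0.9]$ moderate, $(0.9, 1]$ high — the boundary 0.9 itself counts
as moderate ("high" requires strictly greater). A closed-form binormal
AUC, $\Phi\big((\mu_+-\mu_-)/\sqrt{\sigma_+^2+\sigma_-^2}\big)$, serves
as the theoretical center for Monte-Carlo checks.

## Reproducibility and problem sizes

A single master seed controls a whole run. Per-patient and per-replicate
streams are derived from it by a fixed integer recurrence, so patient
$k$'s draws do not depend on how many patients precede it, and replicate
seeds never collide with the master stream.

Problem sizes used by the test suite and acceptance script are chosen to
give stable statistics at interactive runtimes: 2,000 replicates for the
AUC reproduction (Monte-Carlo SE ≈ 0.001), 10,000 null simulations for
the ANOVA type-I calibration (binomial SE ≈ 0.2 percentage points),
60–100 Monte-Carlo fits per SNR level for the bias/variance ordering
checks, and 10,000 draws for distributional consistency of the truth
sampler.

## Known limitations

- The generator's group SDs describe *between-patient* spread of fitted
  parameters; the package re-creates that spread from truth variation
  plus measurement noise, so the simulated fitted-parameter SDs are close
  to, but not exactly, the nominal values.
- The segmented estimator's bias is curve-level and deterministic; at
  parameter combinations outside the asymptotic regime (slow $D^*$) both
  its accuracy claims and the grading conclusions degrade, and the
  package reports rather than hides this (fit flags, configurable
  threshold).
- Empirical tables from any single in-vivo study are not exactly
  reproducible from summary statistics; stochastic checks target the
  binormal-theoretic centers of the published moments, with tolerances
  documented in the tests.
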