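# ivimgrade

Intravoxel incoherent motion (IVIM) diffusion-weighted MRI separates the
signal decay of tissue water diffusion from that of pseudo-random capillary
perfusion. In esophageal squamous cell carcinoma (ESCC), the perfusion
fraction rises and the tissue diffusivity falls as tumors become less
differentiated, so IVIM parameters are candidate non-invasive markers of
pathological grade. How those parameters are *estimated* matters: the
classical **segmented (mono-exponential) fit** and the **full bi-exponential
fit** give systematically different answers on the same decay curves.

`ivimgrade` is for imaging methodologists who want to compare those two
estimation strategies on a realistic, fully synthetic esophageal-tumor
cohort — no patient data required — and for anyone who wants to fit IVIM
parameters to their own region-of-interest (ROI) decay curves.

## The model

The relative signal at diffusion weighting *b* (s/mm²) is

```
S_b / S_0 = f · exp(−b·D*) + (1 − f) · exp(−b·D)
```

with *D* the true diffusion coefficient (mm²/s), *D\** the pseudo-diffusion
coefficient (mm²/s, typically ≳10× *D*), and *f* ∈ [0, 1] the perfusion
fraction. Above a threshold (conventionally b > 200 s/mm²) the perfusion
term has decayed and the curve follows the asymptote
`S_b/S_0 = (1 − f) · exp(−b·D)`.

Two estimators are implemented:

- **Segmented** (`fit_mono_segmented`): ordinary least squares of
  log signal on *b* over the high-b points gives *D*; the extrapolated
  b = 0 intercept gives *f* = 1 − intercept; then *D\** comes from a
  one-dimensional bounded least squares with *D* and *f* held fixed.
- **Full** (`fit_bi_full`): simultaneous bounded Levenberg–Marquardt
  nonlinear least squares of all three parameters over all b values,
  initialized from the segmented estimates.

Around them sit a synthetic-cohort generator (grade-specific truncated
normal parameter distributions, Rician magnitude noise with per-b NEX
averaging, 9 ROIs per patient with measure-then-average pooling), the
grading statistics (Shapiro–Wilk gate, one-way ANOVA with Fisher's LSD
post hoc or Kruskal–Wallis, Spearman correlation with grade), and pairwise
ROC analysis with Youden-index cutoffs.

## Worked example

Fit a noise-free curve generated from the poorly-differentiated group
means, then run the full simulate → fit → analyze pipeline:

```r
library(ivimgrade)

p <- ivim_params(D = 1.05e-3, D_star = 1.25e-2, f = 0.32)
curve <- ivim_signal_curve(p, default_scheme())
fit_mono_segmented(curve)
#> IVIM mono fit: D = 1.057 x10^-3, D* = 1.276 x10^-2 mm^2/s, f = 0.316 (rss 4.84e-06)
fit_bi_full(curve)
#> IVIM bi fit: D = 1.05 x10^-3, D* = 1.25 x10^-2 mm^2/s, f = 0.320 (rss 2.47e-32)
```

The segmented fit carries a small asymptotic bias (residual perfusion
leaks into the b = 400 point), while the full fit recovers noise-free
truth exactly — the core trade-off the package exists to quantify: under
noise the full fit pays for its flexibility with higher variance.

```r
rep1 <- run_reproduction(run_config(cohort = cohort_config(seed = 42)))
rep1$table1[rep1$table1$parameter == "f", c(1:2, 9:10)]
#>  parameter model  test omnibus_p
#>          f  mono ANOVA  3.67e-05
#>          f    bi ANOVA  9.70e-08
head(rep1$table2[rep1$table2$parameter == "f" & rep1$table2$model == "mono", ], 1)
#>  comparison parameter model cutoff   auc sensitivity specificity direction band
#>    PD vs WD         f  mono  0.209 0.929       0.929        0.95 greater-is-positive high
```

At seed 42 the simulated perfusion fraction separates poorly- from
well-differentiated tumors with AUC 0.929 at a cutoff of f = 0.209 —
the same qualitative picture as in vivo: f is the strongest grade
discriminator, D* the weakest-behaved parameter.

A thin command-line wrapper lives at `inst/cli/ivim-grade.R`
(`simulate`, `fit`, `reproduce`, `replicate` subcommands); `fit` accepts
external `curves.csv` files (columns `b,signal`, optional `roi_id`) so
real decay curves can be analyzed the same way.

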