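# spectracal

Multivariate spectral calibration workbench for two-component mixtures with
strongly overlapping UV absorption spectra.

When two analytes absorb across the same 200–260 nm window, no single
wavelength quantifies either of them. The chemometric workflow is: build a
calibration set that spans the joint concentration space, measure full
spectra (301 points at 0.2 nm), and fit a multivariate model **X → Y** from
the absorbance block to the concentration table. `spectracal` implements
that workflow end to end, for people developing or stress-testing such
methods:

* **Design & sampling** — the 5-level × 2-factor multilevel calibration
  design (25 mixtures over 5–25 µg/mL), Latin hypercube and Monte Carlo
  validation plans with stratum-occupancy and space-coverage diagnostics.
* **Preprocessing** — Savitzky–Golay smoothing and derivatives, SNV,
  mean-centering, PCA homogeneity diagnostics.
* **Models** — NIPALS PLS2 with leave-one-out RMSECV latent-variable
  selection; genetic-algorithm wavelength selection with a penalized-RMSECV
  fitness (GA-PLS, fitness `RMSECV + λ·k/p`, λ = 0.05) or an
  information-complexity fitness on the cross-validated residual covariance
  (GA-ICOMP-PLS, `ICOMP = −2 log L + 2 C₁(Σ̂)`); a p-6-2 tanh/linear neural
  network trained by Levenberg–Marquardt; MCR-ALS bilinear curve resolution
  under non-negativity with lack-of-fit reporting.
* **Evaluation** — RMSEC/RMSECV/RMSEP, recovery statistics (%R, SD, %RSD,
  %RE, r, slope/intercept), pooled-variance t and variance-ratio F method
  comparison, relative RMSEP reduction.
* **Synthetic data** — a Beer–Lambert mixture generator (Gaussian-band pure
  spectra, additive/scatter/baseline noise, optional plasma-like
  interferent) so the whole pipeline runs and is tested without any
  instrument data.

Everything tabular goes in and out as tibbles; models have broom-style
`tidy()`/`glance()` methods and `autoplot()` ggplot2 graphics.

## Worked example

Simulate a complete study (25-mixture calibration design, 13-point Latin
hypercube validation set, bench-level noise), pick the latent-variable
count by leave-one-out cross-validation, fit PLS and evaluate:

```r
library(spectracal)

b <- make_study(seed = 1, grid = wavelength_grid(200, 260, 1))
#> <study_bundle> seed 1: 25 calibration + 13 LHS / 13 MC validation mixtures

cv <- loocv(b$calibration$spectra, b$calibration$concentrations, max_lv = 6)
selected_lv(cv)
#> [1] 3

fit <- fit_pls(b$calibration$spectra, b$calibration$concentrations,
               n_lv = selected_lv(cv))
evaluation_report(predict(fit, b$validation_lhs$spectra),
                  b$validation_lhs$concentrations)
#>     component rmsep mean_r_pct    sd rsd_pct re_pct r slope intercept  n
#> 1 component_a 0.163        100 1.156   1.154  0.902 1 0.987   0.19237 13
#> 2 component_b 0.145        100 0.918   0.916  0.743 1 1.000   0.00784 13
```

Read: with ~0.15 µg/mL prediction error the mean recovery on unseen
validation mixtures is 100% with under 1.2% RSD and under 1% mean relative
error — both overlapping analytes are quantified simultaneously despite
neither having a selective wavelength. `run_study()` repeats this for all
five model families and tabulates the comparison; `compare_sampling()`
contrasts Latin hypercube against Monte Carlo validation sampling
(occupancy, spread, and RMSEP stability across repeated draws).

A thin command-line front end over the same functions lives at
`inst/cli/spectracal.R` (subcommands `design`, `sample`, `simulate`,
`preprocess`, `fit-pls`, `evaluate`, `run-study`, `compare-sampling`).

The methods vignette (`vignettes/spectral-calibration-methods.Rmd`)
documents the models, their assumptions, every tunable default, and what
the synthetic generator does and does not emulate.

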