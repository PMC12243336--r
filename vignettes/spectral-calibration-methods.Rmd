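---
title: "Methods: multivariate calibration of overlapping UV mixtures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multivariate calibration of overlapping UV mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectracal)
```

# The problem

Two UV-absorbing analytes whose spectra overlap almost completely cannot be
quantified at a single wavelength. The classical chemometric answer is to
measure full spectra (here 200--260 nm at 0.2 nm, 301 variables), build a
calibration set that spans the joint concentration space, and fit a
multivariate model mapping spectra to concentrations. `spectracal`
implements that workflow end to end: design, sampling, preprocessing, five
calibration models, figures of merit, and a synthetic data generator that
makes every step testable without instrument data.

# Study design and sampling

**Calibration.** The calibration set is a multilevel multifactorial design:
five concentration levels per component, coded $-2\dots 2$ and mapped
linearly onto 5--25 µg/mL. For two components the cyclic multilevel
construction coincides with the $5\times5$ full factorial, so
`multilevel_design()` generates the full factorial: 25 runs, each level
appearing exactly five times per factor.

**Validation.** `lhs_sample()` draws a Latin hypercube plan: each axis is
cut into $n$ equal-width strata ("equal probability" under the uniform
marginal), the strata are permuted independently per axis, and one point is
placed uniformly inside each stratum. The default $n = 13$ keeps the
conventional roughly 2:1 calibration:validation split (25:13 = 65.8%:34.2%).
`mc_sample()` is the unstratified control. The number 13 is adopted as a
study convention, not derived from a rule. For a 13-point Monte Carlo draw
the probability that all 13 strata of one axis are occupied is
$13!/13^{13} \approx 2.06\times10^{-5}$, so Monte Carlo plans essentially
always leave holes whereas the hypercube never does —
`coverage_report()` measures exactly this.

**Isolating the sampling effect.** `compare_sampling()` fixes one
calibration realization and model per master seed and redraws only the
validation plans and their spectra across repeats. Refitting the
calibration every repeat would inject calibration-noise variance common to
both sampling methods and swamp the placement signal; with the calibration
held fixed — which also matches a study in which a single calibration set
exists and only the validation strategy varies — the standard deviation of
RMSEP across repeats is consistently no larger for the hypercube plans.
The effect is real but small (a few percent of the RMSEP SD), so the
comparison needs on the order of a thousand repeats to resolve; the
package default of 50 repeats reports the diagnostics but is not a
hypothesis test.

# Preprocessing

`savgol()` is Savitzky--Golay filtering: a local least-squares polynomial
(default cubic, 11-point window) evaluated at each grid point, with edge
points taken from the polynomial fitted to the nearest full window so the
grid never shrinks. Derivatives are the analytic derivatives of the local
polynomial, scaled by `step_nm^-d` to grid-independent AU/nm$^d$. The
implementation delegates to `signal::sgolayfilt()`, which matches a
brute-force local-fit oracle to $10^{-12}$ at every point including edges —
the test suite asserts this.

`snv()` standardizes each spectrum to mean 0, SD 1 ($n-1$ denominator).
It removes multiplicative scatter and path-length effects and is invariant
to positive affine transforms of a spectrum. **It is deliberately not in
the default pipeline.** In a strictly bilinear two-analyte system the SNV
image of a spectrum depends only on the concentration *ratio*: the overall
intensity, which carries the second degree of freedom, is divided out.
Feeding SNV output to PLS in our simulations raised calibration error by an
order of magnitude. On real instruments, where path-length and scatter
variation corrupt the scale anyway, SNV can pay for itself; the step is
available as `preprocess_pipeline(x, c("savgol", "derivative", "snv"))`.
The default chain is smoothing + first derivative: the first derivative
removes per-sample baseline offsets and sharpens overlapped bands while
preserving linearity in the concentrations. The second derivative is
supported but amplifies noise. When mean-centering is requested together
with SNV it is applied after SNV.

`pca_summary()` reports SVD scores and variance percentages of the
mean-centered block, used as a homogeneity diagnostic for
calibration/validation sets before modeling.

# PLS and latent-variable selection

`fit_pls()` is classical NIPALS PLS2: both blocks mean-centered, weights
and scores extracted per latent variable with deflation of X and Y,
coefficients $B_k = W_k (P_k^\top W_k)^{-1} Q_k^\top$ for every nested LV
count. Scores are mutually orthogonal; at full usable rank predictions
coincide with ordinary least squares (tested against the normal-equations
oracle). Rank deficiency below the requested LV count is an error in
`fit_pls()`; inside cross-validation loops extraction instead truncates
gracefully (extra LVs carry no information), so CV curves over rank-limited
folds remain defined.

`loocv()` pools squared hold-out errors over samples and responses,
$\mathrm{RMSECV}_k = \sqrt{\sum e^2 / (nq)}$, and selects the LV count at
the global minimum, ties broken toward fewer LVs. RMSEC divides by $n$;
this denominator convention is a documented choice.

# Wavelength selection

Both selectors are genetic algorithms over binary inclusion masks:
size-2 tournament selection, uniform crossover, per-bit mutation (default
1%), elitism 1 (which makes best-so-far fitness monotone), population 30.
The initial population is random masks at 50% density plus one all-ones
chromosome, so the full-spectrum baseline is always dominated or matched.
All-zero chromosomes are repaired by flipping one random bit. Block
("window") selection is supported via `window_size`.

**GA-PLS** (`ga_pls()`, default 100 generations, multi-restart) minimizes
the penalized objective $\mathrm{RMSECV} + \lambda k/p$ with
$\lambda = 0.05$. The penalty's functional form (normalized selected count)
is a design choice: it keeps $\lambda$ scale-free in the number of
wavelengths.

**GA-ICOMP-PLS** (`ga_icomp_pls()`, default 50 generations) scores a mask
by the information-complexity criterion of the leave-one-out PLS residuals:
$\mathrm{ICOMP} = -2\log L + 2\,C_1(\hat\Sigma)$ with
$\hat\Sigma = E^\top E/n$, the profiled Gaussian likelihood, and Bozdogan's
covariance complexity
$C_1(\Sigma) = \tfrac{q}{2}\log(\mathrm{tr}\,\Sigma/q) -
\tfrac12\log\det\Sigma$ — the log of the arithmetic-to-geometric mean ratio
of the eigenvalues, zero iff $\Sigma$ is spherical. Using *cross-validated*
residuals makes the criterion see generalization error; both analytes are
modeled jointly ($q = 2$) because $C_1$ vanishes identically at $q = 1$.
A singular $\hat\Sigma$ receives a single $10^{-12}$ ridge and the score is
flagged. The LV count is held fixed during the search (selection is over
wavelengths, not model size).

# The neural network

`fit_ann()` trains a `p`-6-2 feed-forward net (tanh hidden, linear output)
by Levenberg--Marquardt with an analytic Jacobian: solve
$(J^\top J + \mu I)\delta = J^\top e$, multiply $\mu$ by 10 on a rejected
step and divide by 10 on an accepted one; stop at the epoch budget (default
500), the MSE goal, or $\mu$ overflow. Accepted steps strictly decrease the
training MSE, and the Jacobian is verified against central finite
differences. Inputs and outputs are min-max scaled to $[-1,1]$ on the
training partition only; samples are partitioned 70/15/15 (round-half-up,
so 25 samples give 18/4/3) by seed. Early stopping is available but off by
default; the validation split is monitored and reported.

Two robustness choices deserve explanation, because both were adopted after
the naive configuration measurably failed:

* **Input-layer initialization is scaled by `1/n_inputs`.** With hundreds
  of spectral inputs, unscaled uniform $[-0.5, 0.5]$ weights put the hidden
  units deep into tanh saturation before training starts, and the trained
  net generalizes erratically.
* **The default fit is a 3-member committee.** A heavily over-parameterized
  net that interpolates a couple of dozen training mixtures exactly still
  carries an initialization-dependent ripple between the training points —
  the nonlinear component of the random initial function survives training
  because it lies in the null space of the interpolation constraints.
  Averaging three members (distinct derived init seeds, shared partition
  and scaling) cancels most of it: on noise-free synthetic mixtures the
  validation mean recovery moves from 99.4--100.0% (single net, worst
  inits) to 99.95--100.05% across seeds. `n_restarts = 1` restores the
  single-net behavior.

# MCR-ALS

`mcr_als()` factorizes the absorbance block $D \approx C S^\top$ under
non-negativity on both factors. Each half-update solves exact non-negative
least squares per column (Lawson--Hanson active set via
`pracma::lsqnonneg()`), never clipping, which is what makes the percent
lack of fit $\mathrm{lof} = 100\sqrt{\sum e^2/\sum d^2}$ monotone
non-increasing. Convergence is declared when the *relative* change in lof
between sweeps drops below the tolerance (default 1%, the conventional
residual-change criterion; "relative" is a documented reading of that
convention). Reported alongside are the variance explained
$r^2 = 100(1-(\mathrm{lof}/100)^2)$ — which analytically ties a 5.91%
fitting error to 99.65% variance explained — and the residual SD
$\sqrt{\sum e^2/(np)}$ (a documented convention; no formula is standard).
Initialization (`init_profiles()`) picks maximum-dissimilarity spectra:
largest-norm row first, then rows maximizing the residual after projection
onto the span of those already chosen.

**Quantification.** Bilinear factorizations of strictly positive mixtures
are determined only up to an invertible linear transform: with
concentrations spanning 5--25 µg/mL (never touching zero) and heavily
overlapped bands, non-negativity does not pin the rotation, so a
*univariate* regression of one resolved column on one analyte provably
cannot recover concentrations (we measured 10--15% RSD noise-free).
`quantify_from_mcr()` therefore regresses each analyte's known calibration
concentrations on *all* resolved contribution columns jointly; any residual
rotation is absorbed exactly and noise-free recovery is 100.00 ± 0.01%.
Component-to-analyte assignment (reported as an attribute) still uses the
best spectral correlation against calibration-regressed pure-component
estimates, and is an error when ambiguous. True profile *recovery* (not
just prediction) additionally needs selective channels and near-zero
concentrations; the planted-spectra tests construct exactly that regime.

# Figures of merit and method comparison

`rmse()` is $\sqrt{\sum(\hat y - y)^2/n}$ over whichever sample set is
relevant (RMSEC/RMSECV/RMSEP). `recovery_stats()` reports per-sample
recoveries $100\,\hat y/y$, their mean, SD ($n-1$) and RSD, the mean
absolute relative error (%RE — the signed-mean variant is a documented
alternative), the Pearson $r$ of predicted vs actual (`NA`, never 0, when
undefined), and the OLS slope/intercept of predicted on actual.
`compare_methods()` is the pooled-variance two-sample $t$ test plus the
variance-ratio $F$ test (larger variance in the numerator), with critical
values computed from distribution quantiles at runtime — for two groups of
five, $t_{0.975,8} = 2.306$ and $F_{0.95}(4,4) = 6.39$. A paired $t$ is
available since study descriptions vary on this point.
`rmsep_reduction()` is the percent reduction versus a baseline model.

# The synthetic generator

`simulate_mixtures()` implements Beer--Lambert mixing
$A = C S^\top(1+\varepsilon_{\mathrm{scatter}}) + \mathrm{baseline} +
\mathrm{noise}$. The default component pair (Gaussian bands at 210/240 nm
and 205/225 nm) reproduces the strong-overlap regime — cosine similarity
of the normalized pure spectra ≈ 0.93 — and the molar scale is normalized
so 15 µg/mL gives a 0.5 AU peak, a typical bench mid-range absorbance.
These bands are synthetic stand-ins, not measurements of any real drug
pair, and the manifest written by `write_study()` flags them as such. At
the 25+25 µg/mL corner the mixture peaks near 1.6 AU, at the upper edge of
a plausible linear range. Noise defaults are bench-typical: additive
0.002 AU, 1% multiplicative scatter, baseline slope SD $10^{-4}$ AU/nm.
The plasma surrogate adds one broad random band around 210 nm plus doubled
additive noise — residual matrix absorption after protein precipitation,
with no attempt to model the extraction chemistry. With every noise source
at zero the map is exactly linear, which is what the exact-recovery test
regime relies on. Negative noisy absorbances are clamped at zero by
default (raw spectra are non-negative by contract); the unclamped path
exists for characterizing the noise model itself.

What the generator does *not* emulate: instrument line shapes, wavelength
calibration error, stray light, detector nonlinearity, pH/solvent effects,
or real excipient interference. Tests passing on this generator therefore
demonstrate correctness of the algorithms under the stated noise model,
not performance on any particular instrument's data.

# Problem sizes and numerical choices

End-to-end model runs in the test and acceptance suites use a 1-nm grid
(61 points) rather than the 0.2-nm acquisition default: the code paths are
identical and every algorithm's cost drops by a factor of ~5--25, which is
the package's chosen desk-scale working size. Design/grid/partition
arithmetic is always checked at the canonical sizes (301 points, 25 runs,
13 strata, 18/4/3). GA runs in tests use reduced populations/generations;
the defaults (30×50 ICOMP, 30×100 penalized) remain the study
configuration. Other numerical conventions collected here: NIPALS
convergence $10^{-12}$ on the inner vector iteration with a 500-iteration
cap; LV ties break toward fewer; LM damping starts at $10^{-3}$ and aborts
above $10^{10}$; ICOMP ridge $10^{-12}$; MCR tolerance is relative and
configurable down to arbitrarily small values for exactness tests; all
stochastic functions take explicit integer seeds and no global RNG state
leaks (`withr::with_seed` throughout).

# Known limitations

* Only two-component systems are supported in the design module; the
  models themselves are agnostic to $q$.
* MCR quantification requires a calibration block inside the factorized
  matrix; it does not operate on resolved profiles alone.
* The GA does not co-optimize the LV count, by design.
* The sampling comparison's SD contrast is a small effect; at few repeats
  its sign is noise.
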