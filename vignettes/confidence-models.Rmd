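---
title: "Observer models of categorization confidence: models, likelihoods, fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Observer models of categorization confidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confobs)
```

## The experimental paradigm

`confobs` models behavior in a two-task orientation-categorization paradigm
with combined category-and-confidence reports. On every trial one of two
equiprobable categories generates a stimulus orientation $s$ (degrees; 0 =
horizontal, positive = rightward tilt):

* **Task A** (mean discrimination): $s \sim N(-4°, 5°)$ under category 1,
  $s \sim N(+4°, 5°)$ under category 2.
* **Task B** (spread discrimination): $s \sim N(0°, 3°)$ under category 1
  (narrow), $s \sim N(0°, 12°)$ under category 2 (wide).

These design values put the noiseless ideal observer's accuracy near 79% in
both tasks (`ideal_observer_accuracy()` computes the closed forms). Category
1 is the leftward (A) or narrow (B) category; the ideal decision variable
$d$ (below) is positive for category 1, so the observer "chooses category 1
when $d > 0$" and, equivalently in Task A, when the measurement is
*negative*. Stimulus reliability (Gabor contrast or ellipse eccentricity)
takes one of six values per trial, drawn uniformly.

The subject answers with a single button press $r \in \{1,\dots,8\}$:
responses 1–4 are category 1 with confidence 4 ("very high") down to 1
("very low"), responses 5–8 category 2 with confidence rising again. A
subject completes 5 sessions of both task parts; each part alternates
category-training blocks (choice only, full stimulus strength, feedback)
with testing blocks, plus one confidence-training block — 2880 / 240 / 4320
category-training / confidence-training / testing trials in the default
(experiment-1) structure. Only testing trials are analyzed; training trials
are generated for structural fidelity only.

## The measurement model

The observer receives a noisy measurement $x \sim N(s, \sigma^2(c, s))$.
Measurement noise decreases with reliability $c$ through a reparameterized
power law anchored at the lowest and highest reliabilities used
($\sigma_L$, $\sigma_H$, curvature $\beta$), plus an
orientation-dependent term peaking at oblique orientations:

$$\sigma(c,s) = \sqrt{\sigma_L^2 + (\sigma_L^2-\sigma_H^2)
\frac{c^{-\beta}-c_L^{-\beta}}{c_L^{-\beta}-c_H^{-\beta}}}
 + \psi\,\bigl|\sin(\pi s / 90°)\bigr|.$$

A nonparametric variant replaces the power law with one free s.d. per
reliability level. Gaussian (rather than circular Von Mises) noise is a
deliberate approximation: the stimulus range is a small fraction of the
orientation circle.

## The model family

All models share the measurement stage and a lapse model, and differ in the
decision variable to which confidence criteria are applied.

**Bayesian models.** The log posterior ratio
$d = \log p(C=1\mid x) - \log p(C=2\mid x)$ has closed forms:
$d_A = 2x\mu_1/(\sigma^2+\sigma_1^2) + \text{log-prior}$ and
$d_B = \tfrac12\log\frac{\sigma^2+\sigma_2^2}{\sigma^2+\sigma_1^2} -
\frac{(\sigma_2^2-\sigma_1^2)x^2}{2(\sigma^2+\sigma_1^2)(\sigma^2+\sigma_2^2)}
+ \text{log-prior}$. Responses follow from comparing $d$ to criteria
$k_1 < \dots < k_7$, with $k_4$ the category criterion. Three strengths of
the Bayesian confidence hypothesis differ in how many criterion sets exist:
*ultrastrong* (one symmetric set shared by tasks; 4 free parameters),
*strong* (one symmetric set per task; 8), *weak* (symmetric for A, free for
B; 11). The *d-noise* variants add $\eta_d \sim N(0, \sigma_d^2)$ to $d$ on
every trial, marginalized over a 101-point grid.

**Heuristic boundary models.** Fixed, Lin and Quad place criteria directly
in measurement space: $b_r = k_r$, $k_r + m_r\sigma$, or $k_r +
m_r\sigma^2$. Fixed is nested in both Lin and Quad at zero slopes, and in
Task A the no-d-noise Bayesian boundaries are exactly a Quad model in
$\sigma^2$ (both identities are regression tests).

**Orientation estimation.** The observer computes the MAP estimate
$\hat s = \arg\max_s N(s; x, \sigma^2)\,(p(s|C{=}1)+p(s|C{=}2))$ and applies
criteria to $\hat s$ (to $|\hat s|$ in Task B).

**Linear neural readout.** A Poisson population with Gaussian tuning
(s.d. $\sigma_{TC}$, gain $g = 1/\sigma^2$) read out with weights
proportional to preferred orientation yields an approximately Gaussian
decision variable $z$ with mean $a\,g\,s\sqrt{2\pi\sigma_{TC}^2}$ and
variance $a\,g\sqrt{2\pi\sigma_{TC}^2}(\sigma_{TC}^2+s^2)$; criteria act on
$z$ directly (no measurement $x$ exists in this model).

**Precision hybrid.** Confidence criteria act on
$v = \omega/\sigma^2 + 1/(1+e^{-|d|})$, a weighted mixture of measurement
precision and perceived probability of being correct; the category comes
from $d$ against an ultrastrong-style category criterion. This family
excludes the orientation-dependent noise term.

Structural flags orthogonal to the family: separate believed (inference)
versus generative (measurement) noise; free category beliefs (fitted
$\sigma_C$ and log prior ratio); choice-only response mode (the category
criterion only, with a reduced lapse model).

### Response probabilities

For boundary models, the probability of response $r$ is the mass of
$N(x; s, \sigma^2)$ between consecutive measurement-space boundaries —
Task A partitions the line ($b_0 = -\infty$), Task B partitions the
half-line on $|x|$ ($b_0 = 0$, each region the union of two symmetric
intervals). Criteria are translated to measurement space by closed-form
inversion (Bayesian families; the hybrid reduces to the same inversion
after mapping its $v$-criteria to $|d|$-criteria), by construction
(Fixed/Lin/Quad), or via a lookup table (orientation estimation). The
linear neural model integrates the $z$ distribution between its criteria.

### Lapses

Three mutually exclusive lapse events mix with the core response
distribution: a *full lapse* (`lambda_full`; category uniform, confidence
drawn from the 4-level distribution interpolating linearly between endpoint
weights `lambda_1` and `lambda_4`, renormalized to sum 1), a *confidence
lapse* (`lambda_conf`; core category marginal kept, confidence uniform) and
a *repeat lapse* (`lambda_repeat`; the previous response is repeated).
Rates add because the events are disjoint per trial. On the first trial of
a block there is no previous response; the repeat mass is renormalized over
the remaining components. Presentation order is defined by the
session/block/trial keys, so the likelihood is invariant to row order and
sensitive to presentation order exactly through the repeat lapse. With
`lambda_full > 0` every response retains strictly positive probability,
which also guards the zero-mass regions produced by unreachable criteria.

## Parameterization and priors

`param_table()` lists each model's free parameters with their ranges.
Width-like parameters ($\sigma_L$, $\sigma_H$, $\beta$, $\sigma_d$,
$\sigma_{TC}$, $a$, believed category s.d.s) are sampled in log space;
priors are uniform on the sampling scale (hence log-uniform on the natural
scale for those), over deliberately wide ranges: s.d.-like parameters 0.1°
to 50°, Bayesian criteria $[-20, 20]$ in log-odds, measurement-space
criteria and slopes $[-90, 90]$ (degrees, or degrees per $\sigma$-unit),
lapse rates $[0, 0.3]$ except the full-lapse endpoint weights $[0, 1]$,
precision weight $\omega \in [0, 100]$, neural criteria $[-10^5, 10^5]$ on
the readout scale. Boundary parameters are *not* order-constrained;
crossing boundary functions are sorted per $\sigma$, so response regions
never receive negative mass anywhere in the prior box.

## The synthetic-experiment generator

`generate_dataset()` simulates full subjects from any model in the family.
Per-trial draws occur in a documented, fixed order — category, stimulus,
reliability level, measurement (the readout $z$ for the linear neural
model), decision noise where present, then one lapse uniform plus the
lapsed category/confidence uniforms — so identical seeds give bitwise
identical CSVs. Two deliberate choices:

* Responses are generated through the *decision-variable* route (compare
  $d$, $\hat s$, $z$ or $x$ to criteria), while the likelihood evaluates
  the *boundary-inversion* route; the Monte-Carlo agreement tests between
  simulated frequencies and analytic probabilities therefore exercise two
  genuinely different code paths.
* d-noise is drawn exactly from $N(0, \sigma_d^2)$ in simulation; the
  101-point grid is a likelihood-side quadrature (span $\pm 5\sigma_d$,
  capturing all but $\sim 6\times10^{-7}$ of the mass).

Category-training trials are shown at full stimulus strength, outside the
calibrated reliability range; their (never analyzed) responses use noise
clamped to the highest calibrated reliability rather than extrapolating the
power law.

The generator emulates the trial-level statistics and session structure of
the design. It does not emulate learning or fatigue (performance is assumed
stationary), stimulus-specific adaptation, serial dependence beyond the
repeat lapse, or reaction times. Passing tests on synthetic data therefore
validate the machinery — likelihood correctness, sampler calibration,
model distinguishability — not the psychological adequacy of any model for
real subjects.

The `draw_params(source = "plausible")` generating distribution used by the
recovery harness describes a typical subject in this paradigm: noise of
roughly 8–20° at the lowest and 1–3° at the highest reliability, ordered
criteria a few degrees (or a fraction of a log-odds unit) apart, lapse
rates of a few percent. The paper-style alternative of generating from
subjects' fitted posteriors is unavailable without subject data, and raw
draws from the full prior box mostly produce degenerate response patterns
(criteria far outside the stimulus range, 50° noise) that no subject shows;
`source = "prior"` remains available for stress testing.

## Numerical choices

* **Gaussian interval masses** are differences of `pnorm` values (erf-based,
  paired per region); tiny negative differences from rounding are clamped
  at 0. Probabilities must sum to 1 within $10^{-9}$ ($10^{-6}$ for
  interpolated models).
* **Orientation-estimation lookup**: $\hat s(x, \sigma)$ is evaluated on a
  500-point measurement grid × 50-point $\sigma$ grid (defaults), each
  profile by dense-grid maximization (0.1° stimulus grid) with parabolic
  refinement. The MAP profile is monotone but genuinely discontinuous where
  the bimodal posterior switches modes; criteria falling inside a jump are
  mapped to the jump location exactly, reproducing the converged
  zero-width-region limit instead of a grid-width artifact. Halving both
  resolutions changes dataset log likelihoods by well under 0.1 (tested).
  Non-monotone profiles (not observed for the standard tasks) trigger a
  warning and nearest-crossing inversion.
* **d-noise grid**: 101 evenly spaced draws over $\pm 5\sigma_d$ with
  normalized Gaussian weights.
* **Unreachable criteria** (Task B criteria above the maximum of $d_B$)
  collapse to zero-width regions; the lapse mixture keeps the likelihood
  finite.
* **Compiled fast path**: the closed-form boundary families (Fixed, Lin,
  Quad, Bayesian without d-noise) have an Rcpp likelihood kernel that
  evaluates only the observed response's region mass; a pure-R reference
  path covers every family, and the two are asserted equal to machine
  precision in the tests.

## Fitting

`fit_mcmc()` samples the log posterior by univariate stepping-out/shrinkage
slice sampling cycled over coordinates: chains start from random
finite-posterior draws, initial slice widths are 1/10 of each prior range,
stepping out is capped at 50 expansions per side. During burn-in (the first
third of each chain, discarded) widths are tuned once to ~2.5 marginal
s.d.s of the late burn draws and then frozen, which keeps the sampler valid
while roughly halving likelihood evaluations per sweep. Post-burn draws are
thinned to `keep_per_chain` evenly spaced draws; retained draws with log
posterior more than 40 below the maximum are discarded. Convergence is
summarized by split R-hat and bulk effective sample size per parameter
(computed from split-chain autocovariances with Geyer's initial monotone
sequence); R-hat above 1.05 sets a warning flag rather than failing,
mirroring a visual-check workflow but automatable. The desk-scale default
(4 chains × 2000 sweeps) is far below a full-scale analysis (4–7 chains,
$4\times10^4$–$6\times10^5$ samples, 6667 kept per chain); the
configuration object exposes the full-scale settings.

`fit_mle()` is the recovery-harness workhorse: bounded L-BFGS-B inside the
prior box from the best of `n_screen` screened random starts, with a fresh
polish run from each optimum (restarting resets the Hessian approximation
and reliably improves hard cases). `extra_starts` lets callers warm-start
supermodels — the recovery harness seeds Lin and Quad with the fitted Fixed
parameters and zero slopes, which guarantees the nested model never
spuriously outscores its supermodel under a finite iteration budget.

## Model comparison

`information_criteria()` computes AIC, BIC and AICc from the best retained
log likelihood; `waic()` the variance-penalized lppd; `psis_loo()` the
Pareto-smoothed importance-sampling estimate of leave-one-out cross
validation: per trial, the largest $\min(0.2S, 3\sqrt{S})$ importance
ratios are replaced by expected order statistics of a generalized Pareto
distribution fitted to the tail by probability-weighted moments, smoothed
weights are truncated at $S^{3/4}$ times the mean weight, and the tail
shape $\hat k$ is reported per trial (values above 0.7 warn). All metrics
are reported on the expected-log-predictive-density scale (information
criteria multiplied by $-1/2$), so `metric_agreement()` can rank-correlate
them directly. `bootstrap_summed_differences()` aggregates scores across
subjects exactly as a group analysis would: difference from a reference
model per subject, resample subjects with replacement, sum, report the
median and central 95% interval of the sums. Datasets are resampled as
whole subjects (joint-fit scores), matching a design where every subject
contributes one dataset per model grouping.

`run_model_recovery()` closes the loop: generate datasets from each model,
fit every model to every dataset by `fit_mle()`, score by AIC, and check
that the generating model is row-minimal in mean AIC (and report the
fraction of datasets where it wins outright). Group-level random-effects
model selection (protected exceedance probabilities) is deliberately not
implemented; the comparison surface here is scores and their bootstrap.

## Desk-scale problem sizes

The shipped tests validate the pipeline at sizes chosen to run comfortably
on a single desktop core while keeping every check statistically
meaningful; they are the package's reference configuration, not a
limitation of the methods:

* Monte-Carlo likelihood validation: $10^5$ measurement draws per
  (task × reliability × stimulus) condition, all model families, agreement
  within 4 binomial standard errors on ≥ 95% of response cells.
* Sampler calibration: 20 replicate 4320-trial datasets from the Quad
  observer in choice-only mode (8 free parameters), single chains of a few
  hundred sweeps; ≥ 90% of generating parameters inside central 95%
  posterior intervals. The confidence-mode Quad model (23 parameters) uses
  the same code path; its posterior geometry is exercised by the
  metric-agreement fits.
* Metric agreement: three choice-only models fit by MCMC to four
  4320-trial datasets from distinct generators; AIC, BIC, AICc, WAIC and
  LOO must rank the fits near-identically (Spearman ρ > 0.95).
* Recovery: four confidence-mode families (Fixed, Lin, Quad, weak Bayes)
  on Task B, 4 datasets × 4320 trials per generator, single-restart
  warm-started MLE with a small iteration budget — enough for the
  diagonal-dominance check because between-family AIC gaps are hundreds of
  units at this trial count.

## Known limitations

* Slice sampling is serial per coordinate; models beyond ~40 parameters
  (joint fits with nonparametric noise and split beliefs) mix slowly at
  desk scale and deserve the full-scale chain configuration.
* The orientation-estimation and d-noise models pay a large constant factor
  (lookup tables, 101-fold marginalization) and have no compiled path.
* PSIS-LOO inherits the usual caveat: trials with $\hat k > 0.7$ make the
  LOO contribution unreliable; the comparison table records the per-fit
  maximum.
* The repeat lapse conditions on the previous *observed* response; a
  first-trial convention (renormalization) is documented rather than
  empirically identified.
* Experiments 2–3 per-block structures are presets reproducing the printed
  totals (3240 testing trials) rather than a published block arithmetic.
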