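---
title: "Measuring and modeling serial dependence with serialdep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and modeling serial dependence with serialdep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serialdep)
```

## The measurement model

Serial dependence is quantified as the systematic component of trial-wise
errors as a function of the history predictor $x$ — either $\Delta S$
(previous stimulus minus current stimulus) or $\Delta R$ (previous response
minus current stimulus), wrapped to $(-90^\circ, 90^\circ]$ for
orientations. The model is a first derivative of a Gaussian,

$$y_{ij} = x_{ij}\,\alpha_i\, w\, c\, e^{-(w x_{ij})^2} + e_{ij},
\qquad \alpha_i = \alpha_0 + u_i,\quad u_i \sim N(0, \sigma_u^2),$$

with $c = \sqrt{2}\,e^{0.5}$, the unique constant for which $\alpha$ equals
the height of the curve's peak (at $x = 1/(w\sqrt 2)$). Positive $\alpha$
means attraction toward the previous trial, negative means repulsion. Only
the amplitude carries a subject-level random effect; the width $w$ is
shared. This mirrors the standard finding that subject-to-subject
variability is dominated by amplitude, and random widths are both poorly
identified and practically negligible.

**Estimation.** Given $w$ and the variance ratio
$\lambda = \sigma_u^2/\sigma_e^2$, the model is a linear mixed model that is
closed-form by the Woodbury identity (the per-subject covariance is
$\sigma_e^2(I + \lambda g g^\top)$ with $g$ the unit-amplitude DoG basis).
`fit_multilevel_dog()` therefore profiles an exact likelihood over $w$
(40-point log grid on $(0.005, 0.995)$, then local refinement) with an
inner 1-D profile over $\lambda$. The fit is exact maximum likelihood: at
the chosen width it agrees with `lme4::lmer(y ~ 0 + g + (0 + g | subject))`
to $10^{-6}$ (this equivalence is a unit test).

**Inference.** Reporting $z = \alpha_0/\mathrm{SE}$ against the standard
normal is only calibrated when $w$ is known. When $w$ is estimated, two
corrections are applied, both consequences of the width search maximizing
the apparent amplitude under the null:

* the standard error comes from the curvature of the joint
  $(\alpha_0, w)$ profile likelihood rather than conditioning on $\hat w$
  (confidence-interval coverage at the recovery scale is ~95%);
* the default p-value is a likelihood-ratio test against the no-dependence
  null ($y$ pure noise), referred to $\chi^2_3$ — amplitude, width and the
  random-amplitude variance all exist only under the alternative. In
  1,000-replication null simulations this test rejects at 4–5% at nominal
  5%, whereas the naive conditional z-test rejects at ~15%. The z-based
  p-value is retained as `p_z`, and fixed-width fits keep the plain
  z-test.

The two-condition variant (`fit_conditional_dog()`) gives each condition
its own amplitude (fixed + random) and a width offset, exploiting that the
condition-specific bases have disjoint support so the covariance
factorizes; amplitudes are compared with
$z = (\alpha_0 - k_0)/\sqrt{SE_\alpha^2 + SE_k^2}$.

## Removing stimulus-locked biases first

Orientation reports are biased as a function of the *current* stimulus
alone (repulsion from cardinal and oblique axes). Because $\Delta R$
contains the current stimulus, such biases generate spurious
"response-driven" serial dependence. `residualize_orientation_bias()` fits,
per subject, a sum of three sinusoids of the centered/scaled orientation
(robustly: errors beyond 3 SD of the error mean are down-weighted to 0.1;
frequencies are started from the dominant discrete-Fourier components of
the binned mean error, fitted with Levenberg–Marquardt, with a
fourth-degree polynomial fallback on non-convergence) and subtracts it.
Responses are rewritten as `stimulus + residual error` so all downstream
predictors use bias-free reports. The synthetic generator can inject a
bias from exactly this family, so tests can verify near-exact removal, and
the shuffle-null control (`shuffle_null_amplitude()`) verifies the logic
end to end: with an injected bias, shuffled-order refits "find" a positive
$\Delta R$ amplitude before residualization and nothing after.

Outlier handling follows the usual adjustment-task recipe: errors are
circular differences bounded to $\pm 90^\circ$ by construction; trials with
reaction times below 200 ms or beyond 3.5 per-subject SDs are removed
*together with the immediately following trial* (whose history predictor is
unreliable); errors are demeaned per subject; then an iterative two-sided
Grubbs test ($\alpha = 0.05$, t-based critical value) prunes residual
outliers. RT filtering is per subject, consistent with the per-subject
z-scores. Demeaning precedes Grubbs so the test sees chronic-bias-free
errors.

## Model comparison

$\Delta S$ and $\Delta R$ are nearly collinear, so they are never entered
in one model; instead two single-predictor fits are compared by:

* **rmse permutation test** — observed $\mathrm{rmse}(\Delta S) -
  \mathrm{rmse}(\Delta R)$ against refits with each predictor column
  independently permuted within subject (add-one corrected, two-sided);
* **subject-stratified cross-validation** — 70/30 splits with every
  subject contributing to both sets; the headline number is the fraction
  of iterations where the $\Delta R$ model predicts unseen errors better.
  Note that iterations share the dataset, so this fraction is only
  binomially distributed *across* datasets, not within one — the
  calibration test averages over independent null datasets;
* **dominance analysis** — for designs where the two history signals are
  orthogonal: general dominance (average of sole-model and incremental
  fixed-effects $R^2$) on a random-intercept linear mixed model, on
  75% subject-stratified subsamples restricted to $|\Delta| \le 40^\circ$
  where the DoG is near-linear;
* **AIC / likelihood comparison** — because the competing models are
  non-nested with equal dimension, the likelihood-ratio statistic is
  accompanied by a Vuong-style standardized pointwise statistic with a
  normal reference.

Size-estimation tasks reuse the same machinery with plain (non-circular)
differences, a linear mixed model (`fit_linear_mixed()`, lme4 under the
hood) and linear per-subject bias residualization, after which the
report-vs-truth slope is 1 by construction. Forced-choice dual tasks are
analyzed with d′ per subject × congruency × SNR × |deviation| cell (1/(2N)
extreme-rate correction), linear mixed models on d′, and
incongruent-minus-congruent proportion curves fitted with the conditional
DoG.

## The two simulators

Both models share a three-layer architecture: 180 orientation-selective
channels with circular-normal tuning
$r_\theta = A\,e^{\beta(\cos\Delta - 1)}$ ($\beta = 4.68$, unit peak), a
decision unit that reads the population through a weight vector $W$
(initially uniform, $1/180 \approx 0.0056$), and a response stage adding
Gaussian noise ($\sigma_\omega = 10^\circ$ by default). After each trial:

* **Gain model** — channel amplitudes for the next encoding become
  $G = 1 + \alpha_g e^{\beta(\cos\Delta_{n-1}-1)}$ (one-back); $W$ stays
  uniform. Produces attraction.
* **Two-process model** — amplitudes become
  $A = 1 - \alpha_g e^{\beta(\cos\Delta_{n-1}-1)}$ (adaptation, repulsion),
  and on report trials the readout template
  $w_j \propto c + \alpha_w e^{\beta_w(\cos(X - R_j)-1)}$ (normalized to
  sum 1, offset $c = 0.1$, centered on the *reported* orientation) is
  folded into the weights as $W \leftarrow W\,W_{decay} + w_j$. $W$ is
  never renormalized — decoding is scale invariant and the accumulated sum
  converges to $1/(1 - W_{decay})$. No update follows catch trials or
  nonreported sequence stimuli; adaptation, being sensory, follows every
  stimulus.

**Angle conventions.** Orientation is 180°-periodic, which leaves a real
choice in how differences enter the cosines. The package default is the
*identity* mapping — $\cos$ of the raw difference in degrees, i.e. a
kernel with period 360° in orientation units ($\beta = 4.68$ then
corresponds to a circular SD of ~27.8°, and $\beta_w = 24.5$ to ~11.7°) —
with a *linear* (center-of-mass) readout. These defaults were fixed by
calibration: they are the conventions under which the simulator reproduces
the reference bias magnitudes encoded in the acceptance suite
(gain 0.33 → ≈ +1.3°; adaptation 0.33 → ≈ −2.0°; adaptation 0.14 → ≈
−0.8°; the optimal two-process parameter set → ≈ +1.35° on $\Delta S$;
mean absolute error ≈ 8° at $\sigma_\omega = 10^\circ$). A *doubled-angle*
mapping (`angle_mapping = "double"`) and a circular vector-mean readout
are provided as the wrap-respecting alternative; under them noise-free
decoding is exactly veridical at all 180 orientations (an acceptance
property), but the calibration magnitudes come out substantially different
(repulsion too weak by ~30%, the two-process attraction too weak by half),
so they are not the default.

A consequence of the identity convention is a systematic stimulus-locked
decode bias near the 0°/180° wrap (up to ~20°), closely mimicking the
orientation biases of human observers. It is treated exactly the same way:
simulated errors are residualized before fitting (per-orientation
demeaning in the calibration routines, the sinusoid fit in the
artificial-subject replica). Without this step the bias inflates the
Monte-Carlo variance of fitted amplitudes severely (the stimulus walk is
autocorrelated) and leaks into any predictor containing the current
stimulus.

## Calibration (three steps) and replicas

1. `sweep_gain_factor()` maps $\alpha_g$ (50 steps over 0.05–0.95 at
   10,000 trials per point, by default) to the fitted DoG amplitude under
   each mechanism, with reweighting disabled. Amplitudes are reported at
   the reference width $w = 0.05$; a free width would trade off against
   amplitude (the simulated profiles are broader than the empirical ones,
   free fits settle near $w \approx 0.02$).
2. `optimize_template()` fixes $\alpha_g = 0.14$ (a mild adaptation level
   producing ≈ −0.8°) and grid-searches $\alpha_w \in [0,1]$ (linear) ×
   $\beta_w \in [1,50]$ (logarithmic) to match the binned $\Delta S$ error
   profile to a target DoG (amplitude 1.35°, width 0.05). The default grid
   is 25 × 25 at 2,000 trials per point (~1 minute); all points share the
   stimulus sequence and noise draws, so the surface is nearly
   deterministic (correlation > 0.999 across seeds). The forgetting factor
   is held at 0 here — the template history is introduced only in step 3.
   The recovered optimum sits at $\alpha_w \approx 0.04$–0.08 depending on
   grid resolution: the profile-shape objective prefers slightly weaker
   templates than the amplitude-matching value because the simulated
   profile is broader than the target curve.
3. `optimize_decay()` matches single-trial errors against a reference
   sequence over a $W_{decay}$ grid, sharing the reference's noise seed so
   the objective is deterministic and recovery of a known decay is exact to
   the grid resolution.

`replicate_exp12()` generates artificial subjects on combined
peripheral/foveal designs, residualizes and fits both predictor models: the
two-process model reproduces the $\Delta R$ advantage (positive median
rmse difference), the gain model does not. `replicate_exp5()` uses
six-stimulus sequences with report of the last: conditioning errors on the
previous report versus the last nonreported stimulus separates the models
by sign pattern (two-process: attraction to the report, repulsion from the
stimulus; gain: attraction to the stimulus only).

## Synthetic data: what it does and does not emulate

`generate_design()` builds the seven built-in designs (orientation grids
with exact $\Delta S$ constraints via a constrained random walk — any
scheme satisfying the grid constraint is acceptable, and the walk satisfies
it exactly; catch-trial fractions exact per subject; six-stimulus
sequences; contrast levels; ensemble and retro-cue size designs).
`generate_behavior()` adds a DoG dependence on $\Delta S$ or (sequentially)
$\Delta R$, an optional three-sinusoid orientation bias, log-normal
reaction times matched to typical adjustment tasks (mean ≈ 2.23 s,
SD ≈ 1.26 s), and an optional RT contaminant fraction for filter tests.

The generator emulates the statistical structure the pipeline consumes; it
does not emulate perceptual learning or drift, lapses, motor dynamics of
the adjustment itself, or history effects beyond one trial back. Passing
tests therefore demonstrate correctness of the estimators and controls
under the stated generative assumptions, not that those assumptions
exhaust real data.

## Numerical choices and limitations

* Predictor values exactly at ±90° are assigned +90 (tie-break of the
  circular wrap).
* The width search is bounded to (0.005, 0.995); degenerate fits (one
  subject, zero variance) fall back to $\sigma_u = 0$ closed forms.
* Permutation and chance-performance p-values use the add-one estimator
  $(1 + \#\{\text{null} \ge \text{obs}\})/(n+1)$.
* Grubbs is iterated until no rejection; constant or tiny samples pass
  through unchanged.
* Problem sizes in the test suite (10,000-trial calibration runs, 3-seed
  averages, 1,000-replication null calibrations, 50-seed recovery) were
  chosen so Monte-Carlo error stays well below each tolerance; single
  10,000-trial amplitude fits still carry an SD of ~0.1–0.2° after
  residualization, which is why calibration checks average seeds.
* Known limitation: under the default identity mapping, noise-free
  decoding is veridical only away from the 0/180 wrap; the doubled
  mapping is exact everywhere but does not reproduce the calibration
  magnitudes. The tension is documented rather than hidden — both
  conventions are exposed, and `beta_to_width()` converts concentrations
  to widths under each.
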