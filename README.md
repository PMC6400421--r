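# serialdep

Serial dependence analysis and population-coding models of perceptual
history biases.

## The problem

In adjustment psychophysics (rotate a bar to match a grating, resize a disk
to match an ensemble), the error on trial *n* is not independent of history:
reports are systematically **attracted** toward what the observer just
decided and reported, and **repelled** from stimuli that were merely seen.
Disentangling these forces requires (i) careful measurement — the bias of
error on the previous-minus-current difference, with stimulus-locked
response biases removed first, because they masquerade as dependence on the
previous response — and (ii) generative models that say *where* in the
processing hierarchy each force lives.

`serialdep` implements both halves for researchers analyzing trial-level
behavioral data:

- **Measurement.** Trial-wise errors *y<sub>ij</sub>* (subject *i*, trial
  *j*) are fitted with a first-derivative-of-Gaussian (DoG) curve of the
  history predictor *x<sub>ij</sub>*:

  *y<sub>ij</sub>* = *x<sub>ij</sub>* · *α<sub>i</sub>* · *w* · *c* ·
  exp(−(*w x<sub>ij</sub>*)²) + *e<sub>ij</sub>*,  *α<sub>i</sub>* = *α*₀ + *u<sub>i</sub>*

  with *c* = √2·e<sup>0.5</sup> so that *α* is the curve's peak height in
  degrees, a fixed width *w*, and a subject-level random amplitude
  *u<sub>i</sub>*. The predictor is either ΔS (previous stimulus minus
  current stimulus) or ΔR (previous response minus current stimulus), both
  wrapped to (−90°, 90°]. Estimation is exact profile maximum likelihood
  (closed-form linear mixed model at each width). Supporting machinery:
  RT/Grubbs outlier filters, three-sinusoid orientation-bias and linear
  size-bias residualization, shuffle-null and future-trial controls,
  rmse permutation tests, subject-stratified cross-validation, dominance
  analysis, signal-detection (d′) analyses.

- **Models.** Two data-generating simulators share a three-layer
  architecture (180 orientation-tuned channels → a decision unit reading
  the population through weights *W* → a noisy response stage). The **Gain
  model** raises the sensitivity of channels tuned near the previous
  stimulus (attraction from the bottom up). The **Two-process model**
  *suppresses* those channels (adaptation, repulsion) and instead lets the
  decision unit's readout template persist across trials, centered on the
  previous report with forgetting factor *W*<sub>decay</sub> (attraction
  from the top down). A three-step calibration (gain-factor sweep, template
  grid search, decay matching) fits the free parameters.

Everything is testable without human data: the synthetic-data module
generates the trial designs (orientation grids, Δ constraints, catch
trials, stimulus sequences, contrast and size ensembles) and behavior with
known ground truth.

## Worked example

```r
library(serialdep)

# 1. a synthetic experiment: 10 subjects x 560 trials, orientations on a
#    10-degree grid, consecutive differences within +/-50 degrees
design <- experiment_design("exp1")
trials <- generate_design(design, seed = 1)
truth  <- ground_truth(alpha = 2, w = 0.05, sigma = 10,
                       bias = orientation_bias_default())
behav  <- generate_behavior(trials, truth, seed = 2)

# 2. clean: RT filter, demeaning, Grubbs, orientation-bias residualization
pp <- preprocess_trials(behav)
pp$report
#> Cleaning report:
#>   RT filter: 55 fast/outlier + 55 following (1.96% of trials)
#>   Grubbs: 1 removed; total removed 1.98%
#>   residualization: 10 subject fits

# 3. fit the multilevel DoG on the previous-stimulus predictor
fit <- fit_multilevel_dog(pp$data, "delta_S")
fit
#> DoG fit (delta_S)
#>   alpha0 = 1.815 deg (SE 0.307), z = 5.91, p = 4.34e-14
#>   w = 0.0453 (peak at 15.6 deg), sigma_e = 9.85, sigma_u = 0.58
#>   n = 5479 trials, 10 subject(s), rmse = 9.842, AIC = 40623.4
```

The generating amplitude was 2° at width 0.05; the fit recovers
1.82° ± 0.31 at width 0.045. `alpha0` is the attraction in degrees at the
curve's peak; positive means reports are pulled toward the previous trial.

Simulator, in three lines:

```r
cfg <- simulation_config("two_process", alpha_g = 0.14, alpha_w = 0.08,
                         beta_w = 24.5, w_decay = 0.19, sigma = 10)
sim <- run_simulation(trials, cfg, seed = 3)
sim <- residualize_orientation_bias(sim)$data   # as for real observers
fit_multilevel_dog(sim, "delta_S", fix_w = 0.05)$alpha0
#> [1] 0.9664910
```

Attraction of ~1° toward the previous stimulus, emerging from adaptation
*plus* decisional-template persistence — neither mechanism alone produces
it (set `alpha_w = 0` to watch it flip to repulsion).

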