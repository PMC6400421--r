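# Three-step calibration of the simulators and the two simulation replicas
# used to adjudicate the Gain vs Two-process accounts.
#
# Step 1 sweeps the gain factor and maps it to the fitted DoG amplitude of
# the resulting bias (positive for gain, negative for adaptation).
# Step 2, with a fixed small adaptation, grid-searches the decisional
# template (alpha_w, beta_w) so that the simulated delta_S error profile
# matches a target DoG curve.
# Step 3 picks the forgetting factor W_decay by matching single-trial
# errors against a reference error sequence.

# one long design-like stimulus sequence for calibration runs
.sweep_stimuli <- function(n_trials, style = c("exp1", "exp2", "uniform"),
                           seed = NULL) {
  style <- match.arg(style)
  if (!is.null(seed)) set.seed(seed)
  if (style == "uniform") return(sample(0:179, n_trials, replace = TRUE))
  og <- if (style == "exp1") seq(0, 170, 10) else 0:179
  dg <- if (style == "exp1") seq(-50, 50, 10) else -80:80
  .orientation_walk(n_trials, og, dg)
}

# simulate one observer over a stimulus vector and return (delta_S, error)
.sim_errors <- function(stimuli, config, seed = NULL) {
  tab <- data.frame(subject = "sim", trial = seq_along(stimuli),
                    stimulus = stimuli)
  out <- run_simulation(tab, config, seed = seed)
  ds <- wrap_delta(c(NA, stimuli[-length(stimuli)]), stimuli)
  err <- wrap_delta(out$response, stimuli)
  list(delta_S = ds, error = err, response = out$response)
}

#' Sweep the gain factor against the fitted bias amplitude
#'
#' For each gain factor on the grid, simulates `n_trials` adjustment trials
#' under the chosen mechanism with uniform constant readout weights and fits
#' the DoG to the errors conditioned on the previous-stimulus difference.
#' The gain mechanism produces positive (attractive) amplitudes, the
#' adaptation mechanism negative (repulsive) ones. Amplitudes are reported
#' at the reference width `w_ref` (the calibration target's width), which
#' avoids the amplitude-width trade-off of a free fit; set `w_ref = NULL`
#' to free the width.
#'
#' @param mechanism `"gain"` or `"adaptation"`.
#' @param grid Gain-factor values (default 50 steps over 0.05-0.95).
#' @param n_trials Simulated trials per grid point.
#' @param config Base [simulation_config()]; the model/alpha_g fields are
#'   overridden per grid point and reweighting is disabled.
#' @param style Stimulus-sequence style for the sweep.
#' @param w_ref Reference DoG width for the amplitude fit.
#' @param residualize Remove the stimulus-locked mean error (per presented
#'   orientation) before fitting, as the analysis pipeline does for
#'   behavioral errors. The identity-mapping decoder carries a systematic
#'   orientation-dependent bias which, with autocorrelated stimulus walks,
#'   otherwise inflates the Monte-Carlo variance of the fitted amplitude.
#' @param seed Random seed.
#' @return Data frame of class `gain_sweep` with `alpha_g`, `amplitude`
#'   (degrees), `w` (the width used/fitted).
#' @export
sweep_gain_factor <- function(mechanism = c("gain", "adaptation"),
                              grid = seq(0.05, 0.95, length.out = 50),
                              n_trials = 10000,
                              config = simulation_config(),
                              style = "exp1", w_ref = 0.05,
                              residualize = TRUE, seed = 1) {
  mechanism <- match.arg(mechanism)
  config$model <- if (mechanism == "gain") "gain" else "two_process"
  config$alpha_w <- 0          # uniform template: no decisional reweighting
  config$w_decay <- 0
  out <- lapply(seq_along(grid), function(i) {
    config$alpha_g <- grid[i]
    st <- .sweep_stimuli(n_trials, style, seed = seed + i)
    se <- .sim_errors(st, config, seed = seed + 10000 + i)
    err <- se$error
    if (residualize) err <- err - stats::ave(err, st)
    f <- fit_dog(se$delta_S, err, fix_w = w_ref)
    data.frame(alpha_g = grid[i], amplitude = f$alpha0, w = f$w)
  })
  structure(do.call(rbind, out),
            class = c("gain_sweep", "data.frame"), mechanism = mechanism)
}

#' Optimize the decisional template against a target bias profile
#'
#' Step-2 calibration of the Two-process model: with adaptation fixed at
#' `alpha_g`, grid-search the template amplitude `alpha_w` (linear grid on
#' `[0, 1]`) and concentration `beta_w` (logarithmic grid on `[1, 50]`),
#' simulating `n_trials` responses per grid point and minimizing the summed
#' squared distance between the mean error per previous-stimulus-difference
#' bin and the target curve `dog(delta, target_alpha, target_w)`. During
#' this step the template history is one-back (`w_decay = 0`); the
#' forgetting factor is calibrated afterwards ([optimize_decay()]). All
#' grid points share the stimulus sequence and noise draws (common random
#' numbers), which removes most Monte-Carlo jitter from the surface.
#'
#' @param alpha_g Fixed adaptation strength.
#' @param target_alpha,target_w Target DoG amplitude (degrees) and width.
#' @param alpha_w_grid,beta_w_grid Search grids.
#' @param n_trials Simulated trials per grid point.
#' @param config Base [simulation_config()].
#' @param style Stimulus-sequence style.
#' @param residualize Remove the stimulus-locked mean error before binning
#'   (see [sweep_gain_factor()]); the target profile describes bias-free
#'   errors, so the simulated profile is residualized the same way.
#' @param seed Random seed.
#' @return List of class `template_opt`: `alpha_w_opt`, `beta_w_opt`,
#'   `objective` (matrix alpha_w x beta_w), the grids and the target.
#' @export
optimize_template <- function(alpha_g = 0.14, target_alpha = 1.35,
                              target_w = 0.05,
                              alpha_w_grid = seq(0, 1, length.out = 25),
                              beta_w_grid = exp(seq(log(1), log(50),
                                                    length.out = 25)),
                              n_trials = 2000,
                              config = simulation_config(model = "two_process"),
                              style = "exp1", residualize = TRUE, seed = 1) {
  config$model <- "two_process"
  config$alpha_g <- alpha_g
  config$w_decay <- 0
  st <- .sweep_stimuli(n_trials, style, seed = seed)
  ds <- wrap_delta(c(NA, st[-length(st)]), st)
  bins <- sort(unique(ds[!is.na(ds)]))
  target <- dog(bins, target_alpha, target_w)
  obj <- matrix(NA_real_, length(alpha_w_grid), length(beta_w_grid))
  for (i in seq_along(alpha_w_grid)) {
    for (j in seq_along(beta_w_grid)) {
      config$alpha_w <- alpha_w_grid[i]
      config$beta_w <- beta_w_grid[j]
      se <- .sim_errors(st, config, seed = seed + 1)  # common random numbers
      err <- se$error
      if (residualize) err <- err - stats::ave(err, st)
      prof <- vapply(bins, function(b)
        mean(err[!is.na(ds) & ds == b]), numeric(1))
      obj[i, j] <- sum((prof - target)^2)
    }
  }
  best <- arrayInd(which.min(obj), dim(obj))
  if (diff(range(obj)) < 1e-9)
    warning("objective surface is flat; optimum is not identified")
  structure(list(alpha_w_opt = alpha_w_grid[best[1]],
                 beta_w_opt = beta_w_grid[best[2]],
                 objective = obj, alpha_w_grid = alpha_w_grid,
                 beta_w_grid = beta_w_grid,
                 target_alpha = target_alpha, target_w = target_w,
                 alpha_g = alpha_g, n_trials = n_trials),
            class = "template_opt")
}

#' @export
print.template_opt <- function(x, ...) {
  cat(sprintf(
    "template optimum: alpha_w = %.3f, beta_w = %.1f (target DoG %.2f deg, w %.3f; adaptation %.2f)\n",
    x$alpha_w_opt, x$beta_w_opt, x$target_alpha, x$target_w, x$alpha_g))
  invisible(x)
}

#' Reference error sequence for the decay calibration
#'
#' Generates a single-observer Two-process error sequence at a known
#' forgetting factor, to serve as the reference of [optimize_decay()] when
#' no empirical single-trial errors are supplied.
#'
#' @param w_decay True forgetting factor.
#' @param n_trials Sequence length.
#' @param config Base [simulation_config()] (two-process fields used).
#' @param style Stimulus-sequence style.
#' @param seed Random seed (the same seed must be passed to
#'   [optimize_decay()] so candidate simulations share the noise draws).
#' @return List with `stimuli`, `errors`, `w_decay`, `seed`.
#' @export
make_decay_reference <- function(w_decay = 0.19, n_trials = 5000,
                                 config = simulation_config(
                                   model = "two_process", alpha_g = 0.14),
                                 style = "exp1", seed = 1) {
  config$model <- "two_process"
  config$w_decay <- w_decay
  st <- .sweep_stimuli(n_trials, style, seed = seed)
  se <- .sim_errors(st, config, seed = seed + 1)
  list(stimuli = st, errors = se$error, w_decay = w_decay, seed = seed,
       config = config)
}

#' Optimize the forgetting factor against reference errors
#'
#' Step-3 calibration: for each candidate `W_decay` on the grid, simulates
#' the Two-process model on the reference stimulus sequence (sharing the
#' reference's noise seed, so the objective is deterministic) and minimizes
#' the summed squared difference between simulated and reference
#' single-trial errors.
#'
#' @param reference A [make_decay_reference()] result, or a list with
#'   `stimuli`, `errors`, `seed` and `config` fields (e.g. built from real
#'   single-trial errors).
#' @param grid Candidate forgetting factors.
#' @return List of class `decay_opt`: `w_decay_opt` and the objective
#'   curve.
#' @export
optimize_decay <- function(reference,
                           grid = seq(0.01, 1, length.out = 100)) {
  config <- reference$config
  obj <- vapply(grid, function(d) {
    config$w_decay <- d
    se <- .sim_errors(reference$stimuli, config, seed = reference$seed + 1)
    sum((se$error - reference$errors)^2, na.rm = TRUE)
  }, numeric(1))
  structure(list(w_decay_opt = grid[which.min(obj)], grid = grid,
                 objective = obj), class = "decay_opt")
}

#' Artificial-subject replica of the adjustment experiments
#'
#' Simulates artificial observers responding to combined peripheral- and
#' foveal-design trial sequences under the chosen model, preprocesses their
#' errors exactly like real data (orientation-bias residualization), fits
#' the multilevel DoG with both the previous-stimulus and previous-response
#' predictors, and records the rmse difference `rmse(delta_S) -
#' rmse(delta_R)` per iteration. A positive median difference reproduces
#' the empirical superiority of the previous-response predictor.
#'
#' @param config A [simulation_config()] (the published Two-process optimum
#'   by default when `model = "two_process"`).
#' @param n_iter Number of independent replications.
#' @param n_subjects_each Subjects per design per iteration.
#' @param n_trials_exp1,n_trials_exp2 Trials per subject for the two
#'   designs.
#' @param residualize Apply the orientation-bias residualization before
#'   fitting (as for real data).
#' @param seed Random seed.
#' @return List of class `replica_result`: `rmse_diff` per iteration,
#'   `mean_abs_error` (grand mean over iterations, degrees), per-iteration
#'   amplitudes for both predictors.
#' @export
replicate_exp12 <- function(config = simulation_config(
                              model = "two_process", alpha_g = 0.14),
                            n_iter = 1000, n_subjects_each = 5,
                            n_trials_exp1 = 560, n_trials_exp2 = 440,
                            residualize = TRUE, seed = 1) {
  res <- lapply(seq_len(n_iter), function(it) {
    d1 <- generate_design(experiment_design("exp1",
                                            n_subjects = n_subjects_each,
                                            n_trials = n_trials_exp1),
                          seed = seed + 17 * it)
    d2 <- generate_design(experiment_design("exp2",
                                            n_subjects = n_subjects_each,
                                            n_trials = n_trials_exp2),
                          seed = seed + 17 * it + 1)
    d2$subject <- paste0(d2$subject, "b")
    tab <- rbind(d1[intersect(names(d1), names(d2))],
                 d2[intersect(names(d1), names(d2))])
    tab <- run_simulation(tab, config, seed = seed + 17 * it + 2)
    if (residualize) tab <- residualize_orientation_bias(tab)$data
    mae <- mean(abs(wrap_delta(tab$response, tab$stimulus)), na.rm = TRUE)
    fS <- fit_multilevel_dog(tab, "delta_S")
    fR <- fit_multilevel_dog(tab, "delta_R")
    c(rmse_diff = fS$rmse - fR$rmse, mae = mae,
      alpha_S = fS$alpha0, alpha_R = fR$alpha0)
  })
  m <- do.call(rbind, res)
  structure(list(rmse_diff = m[, "rmse_diff"],
                 mean_abs_error = mean(m[, "mae"]),
                 alpha_S = m[, "alpha_S"], alpha_R = m[, "alpha_R"],
                 n_iter = n_iter, model = config$model),
            class = "replica_result")
}

#' @export
print.replica_result <- function(x, ...) {
  cat(sprintf(
    "%s replica (%d iterations): median rmse(dS)-rmse(dR) = %.4f, mean |error| = %.2f deg\n",
    x$model, x$n_iter, stats::median(x$rmse_diff), x$mean_abs_error))
  invisible(x)
}

#' Sequence-design replica (reported vs nonreported stimuli)
#'
#' Simulates the six-stimulus sequence paradigm (report only the last
#' stimulus of each sequence) and conditions the simulated errors on (a)
#' the orientation reported on the previous trial and (b) the last
#' nonreported stimulus of the current sequence, fitting a conditional DoG
#' with separate amplitudes. The Two-process model predicts opposite signs
#' (repulsion from the nonreported stimulus, attraction toward the previous
#' report); the Gain model predicts attraction to the last stimulus only
#' and no effect of the previous report.
#'
#' @param config A [simulation_config()].
#' @param n_trials Number of sequence trials.
#' @param residualize Remove the stimulus-locked mean error before the
#'   conditional fit (as for behavioral data; without it the decoder's
#'   orientation bias masquerades as dependence on the previous report).
#' @param seed Random seed.
#' @return List of class `exp5_replica`: `alpha_reported`,
#'   `alpha_nonreported`, their SEs, and the underlying conditional fit.
#' @export
replicate_exp5 <- function(config = simulation_config(model = "two_process",
                                                      alpha_g = 0.33),
                           n_trials = 10000, residualize = TRUE, seed = 1) {
  des <- experiment_design("exp5", n_subjects = 1, n_trials = n_trials,
                           catch_fraction = 0)
  tab <- generate_design(des, seed = seed)
  tab <- run_simulation(tab, config, seed = seed + 1)
  seqs <- lapply(tab$sequence_json, jsonlite::fromJSON)
  last_nonrep <- vapply(seqs, function(s) s[length(s) - 1], numeric(1))
  prev_resp <- c(NA, tab$response[-nrow(tab)])
  if (residualize) {
    err <- wrap_delta(tab$response, tab$stimulus)
    err <- err - stats::ave(err, tab$stimulus)
    tab$response <- wrap_orientation(tab$stimulus + err)
  }
  x_rep <- wrap_delta(prev_resp, tab$stimulus)
  x_non <- wrap_delta(last_nonrep, tab$stimulus)
  stacked <- data.frame(
    subject = "sim",
    trial = seq_len(2 * nrow(tab)),
    stimulus = rep(tab$stimulus, 2),
    response = rep(tab$response, 2),
    delta_S = c(x_non, x_rep),
    cond = rep(c("nonreported", "reported"), each = nrow(tab)))
  fit <- fit_conditional_dog(stacked, "delta_S", condition = stacked$cond)
  structure(list(alpha_nonreported = fit$alpha0,
                 alpha_reported = fit$k0,
                 se_nonreported = fit$se_alpha0, se_reported = fit$se_k0,
                 fit = fit, model = config$model, n_trials = n_trials),
            class = "exp5_replica")
}

#' @export
print.exp5_replica <- function(x, ...) {
  cat(sprintf(
    "%s sequence replica: alpha(nonreported) = %.3f, alpha(reported) = %.3f\n",
    x$model, x$alpha_nonreported, x$alpha_reported))
  invisible(x)
}
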