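# Population-coding simulators of serial dependence.
#
# Architecture: 180 orientation-tuned channels (preferred orientations
# 0..179 deg) -> a decision unit reading the population out through a weight
# vector W -> a response stage adding Gaussian motor noise. Two history
# mechanisms are available: a gain increase centered on the previous
# stimulus (Gain model, attraction) or an amplitude suppression centered on
# it (adaptation) combined with a decisional template that re-weights the
# readout toward the previously reported orientation (Two-process model).
#
# Angle conventions. Orientation is 180-degree periodic, but the circular
# kernels admit two mappings of an orientation difference d onto the cosine:
#   "identity": cos(d * pi/180)  - period 360 deg in orientation units; the
#       kernel is broad (beta = 4.68 gives circular SD ~27.8 deg) and the
#       0/180 wrap is *not* a neighbor relation. This is the default: it is
#       the convention under which the simulator's calibration reproduces
#       the reference bias magnitudes, and its systematic edge bias mimics
#       the stimulus-dependent response biases seen in human data (removed
#       by residualization, exactly as for real observers).
#   "double":   cos(2d * pi/180) - the wrap-respecting axial mapping (0 and
#       179 are near neighbors); under this mapping noise-free decoding is
#       exactly veridical at every orientation.
# Readout: "linear" (center of mass of preferred orientations, default) or
# "circular" (vector mean in the mapped angle space).

#' Circular-normal tuning response
#'
#' Response of an orientation-tuned unit, `amplitude * exp(beta *
#' (cos(D) - 1))` with `D` the mapped difference between stimulus and
#' preferred orientation. Maximal (= `amplitude`) at `theta == theta0`.
#'
#' @param theta Stimulus orientation(s), degrees.
#' @param theta0 Preferred orientation(s), degrees.
#' @param amplitude Peak response.
#' @param beta Tuning concentration (width parameter).
#' @param angle_mapping `"identity"` or `"double"` (see Details in
#'   [simulation_config()]).
#' @return Unit response(s).
#' @export
#' @examples
#' tuning_response(45, 45)                     # 1
#' tuning_response(90, 0, angle_mapping = "double")  # orthogonal, ~8.6e-5
tuning_response <- function(theta, theta0, amplitude = 1, beta = 4.68,
                            angle_mapping = c("identity", "double")) {
  m <- if (match.arg(angle_mapping) == "double") 2 else 1
  amplitude * exp(beta * (cos(.deg2rad(m * (theta - theta0))) - 1))
}

# kernel over the 180 preferred orientations, centered at `center`
.channel_kernel <- function(center, beta, mapping, prefs = 0:179) {
  m <- if (mapping == "double") 2 else 1
  exp(beta * (cos(.deg2rad(m * (center - prefs))) - 1))
}

#' Gain modulation profile after a stimulus
#'
#' Amplitude multipliers `1 + alpha_g * k(theta_prev - theta0)` applied to
#' the 180 channels for the encoding of the next stimulus: channels tuned
#' near the previous orientation become *more* responsive, producing an
#' attractive bias.
#'
#' @param theta_prev Previously presented orientation, degrees.
#' @param alpha_g Gain factor (>= 0).
#' @param beta Kernel concentration (defaults to the tuning value 4.68).
#' @param angle_mapping See [tuning_response()].
#' @return Numeric vector of 180 amplitude multipliers.
#' @export
gain_profile <- function(theta_prev, alpha_g, beta = 4.68,
                         angle_mapping = c("identity", "double")) {
  stopifnot(alpha_g >= 0)
  1 + alpha_g * .channel_kernel(theta_prev, beta, match.arg(angle_mapping))
}

#' Adaptation profile after a stimulus
#'
#' As [gain_profile()] with inverted sign: `1 - alpha_g * k(.)`. Channels
#' tuned near the previous orientation are suppressed, repelling the decoded
#' orientation of a similar subsequent stimulus.
#'
#' @inheritParams gain_profile
#' @return Numeric vector of 180 amplitude multipliers (all in
#'   `[1 - alpha_g, 1]`).
#' @export
adaptation_profile <- function(theta_prev, alpha_g, beta = 4.68,
                               angle_mapping = c("identity", "double")) {
  stopifnot(alpha_g >= 0)
  if (alpha_g >= 1)
    stop("alpha_g must be < 1: adaptation would produce negative amplitudes")
  1 - alpha_g * .channel_kernel(theta_prev, beta, match.arg(angle_mapping))
}

#' Decode an orientation from a population response
#'
#' Weighted readout of the population: effective weights are the elementwise
#' product of the population response and the decisional weight vector `W`.
#' With `readout = "linear"` the decoded orientation is the center of mass
#' of the preferred orientations; with `"circular"` it is the weighted
#' vector mean computed in the mapped angle space. Both are invariant to
#' rescaling `W`.
#'
#' @param population_response Non-negative vector of 180 channel responses.
#' @param W Non-negative weight vector of length 180 (decisional readout
#'   weights).
#' @param readout `"linear"` or `"circular"`.
#' @param angle_mapping Mapping used by the circular readout.
#' @return Decoded orientation in `[0, 180)` degrees.
#' @export
decode_orientation <- function(population_response, W = rep(1 / 180, 180),
                               readout = c("linear", "circular"),
                               angle_mapping = c("identity", "double")) {
  readout <- match.arg(readout)
  eff <- population_response * W
  s <- sum(eff)
  if (!is.finite(s) || s <= 0)
    stop("all-zero effective weights: cannot decode")
  prefs <- 0:179
  if (readout == "linear") {
    sum(eff * prefs) / s
  } else {
    m <- if (match.arg(angle_mapping) == "double") 2 else 1
    a <- atan2(sum(eff * sin(.deg2rad(m * prefs))),
               sum(eff * cos(.deg2rad(m * prefs)))) / m * 180 / pi
    a %% 180
  }
}

#' Decisional template weights
#'
#' Normalized circular-normal weight profile centered on the decoded /
#' reported orientation: `w_j = (c + alpha_w * k(X - R_j)) / sum(...)`,
#' summing exactly to 1. The offset `c` keeps all weights strictly positive.
#'
#' @param r_j Reported (decoded) orientation, degrees.
#' @param alpha_w Template peak amplitude (>= 0); 0 gives the uniform
#'   1/180 weights.
#' @param beta_w Template concentration.
#' @param offset Baseline offset `c` (default 0.1).
#' @param angle_mapping See [tuning_response()].
#' @return Weight vector of length 180 summing to 1.
#' @export
template_weights <- function(r_j, alpha_w, beta_w, offset = 0.1,
                             angle_mapping = c("identity", "double")) {
  stopifnot(alpha_w >= 0, beta_w > 0, offset > 0)
  v <- offset + alpha_w * .channel_kernel(r_j, beta_w, match.arg(angle_mapping))
  v / sum(v)
}

#' Update the decisional weight vector
#'
#' Trial-to-trial evolution of the readout weights: after a response the
#' old weights decay by `w_decay` and the fresh template is added
#' (`W' = W * w_decay + w_j`); on trials without a response (catch trials,
#' nonreported stimuli) the weights are untouched. Weights are deliberately
#' not renormalized: decoding is scale-invariant and the accumulated sum
#' converges geometrically to `1 / (1 - w_decay)`.
#'
#' @param W Current weight vector.
#' @param w_j Fresh template from [template_weights()].
#' @param responded Logical: did a report occur this trial?
#' @param w_decay Forgetting factor in `(0, 1]` (multiplies the old weights;
#'   small values forget fast).
#' @return Updated weight vector.
#' @export
update_weights <- function(W, w_j, responded, w_decay) {
  stopifnot(length(W) == length(w_j))
  if (!responded) return(W)
  W * w_decay + w_j
}

#' Simulator configuration
#'
#' Bundles all parameters of the two data-generating models.
#'
#' @param model `"gain"` (gain increase toward the previous stimulus,
#'   uniform constant readout weights) or `"two_process"` (adaptation away
#'   from the previous stimulus plus decisional-template reweighting).
#' @param alpha_g Gain/adaptation factor in `[0, 1)`.
#' @param beta Tuning concentration of the 180 channels (default 4.68).
#' @param alpha_w,beta_w Decisional-template amplitude and concentration
#'   (two-process only).
#' @param offset Template baseline offset `c`.
#' @param w_decay Forgetting factor for the weight history (two-process).
#' @param sigma Response (motor) noise SD in degrees, added to the decoded
#'   orientation on report trials.
#' @param angle_mapping `"identity"` (default; broad kernels, the
#'   calibration-matching convention) or `"double"` (wrap-respecting axial
#'   mapping).
#' @param readout `"linear"` (center-of-mass, default) or `"circular"`.
#' @param adaptation_memory `"one_back"` (profile recomputed from the last
#'   stimulus only, default) or `"accumulate"` (profiles multiply, with
#'   recovery `memory_recovery` pulling amplitudes back toward 1).
#' @param memory_recovery Recovery rate in `(0, 1]` for the accumulate mode.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(model = c("gain", "two_process"),
                              alpha_g = 0.33, beta = 4.68,
                              alpha_w = 0.08, beta_w = 24.5,
                              offset = 0.1, w_decay = 0.19,
                              sigma = 10,
                              angle_mapping = c("identity", "double"),
                              readout = c("linear", "circular"),
                              adaptation_memory = c("one_back", "accumulate"),
                              memory_recovery = 0.5) {
  model <- match.arg(model)
  stopifnot(alpha_g >= 0, alpha_g < 1, sigma >= 0)
  structure(list(model = model, alpha_g = alpha_g, beta = beta,
                 alpha_w = alpha_w, beta_w = beta_w, offset = offset,
                 w_decay = w_decay, sigma = sigma,
                 angle_mapping = match.arg(angle_mapping),
                 readout = match.arg(readout),
                 adaptation_memory = match.arg(adaptation_memory),
                 memory_recovery = memory_recovery),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "%s model: alpha_g=%.3g beta=%.3g alpha_w=%.3g beta_w=%.3g w_decay=%.3g sigma=%.3g\n",
    x$model, x$alpha_g, x$beta, x$alpha_w, x$beta_w, x$w_decay, x$sigma))
  cat(sprintf("  mapping=%s readout=%s memory=%s\n",
              x$angle_mapping, x$readout, x$adaptation_memory))
  invisible(x)
}

# initial model state
.init_state <- function() {
  list(amp = rep(1, 180), W = rep(1 / 180, 180))
}

# integer-stimulus kernel table for speed (rows: stimulus 0..179)
.kernel_table <- function(beta, mapping) {
  m <- if (mapping == "double") 2 else 1
  exp(beta * (cos(.deg2rad(m * outer(0:179, 0:179, "-"))) - 1))
}

#' Simulate a single trial
#'
#' Encodes a stimulus through the (possibly history-modulated) channels,
#' decodes it with the current weights, optionally produces a noisy report,
#' and applies the model's history updates: gain or adaptation keyed to the
#' presented stimulus (affecting the *next* encoding), and — in the
#' two-process model, on report trials only — the decisional-template weight
#' update centered on the reported orientation.
#'
#' @param stimulus Orientation in degrees.
#' @param state List with `amp` (180 amplitude multipliers) and `W`
#'   (readout weights), as from the initial state of [run_simulation()].
#' @param config A [simulation_config()].
#' @param respond Logical: is this a report trial?
#' @return List with `response` (degrees, or `NA` on no-report trials),
#'   `decoded` (noise-free decoded orientation) and the updated `state`.
#' @export
simulate_trial <- function(stimulus, state, config, respond = TRUE) {
  k <- .channel_kernel(stimulus, config$beta, config$angle_mapping)
  pop <- state$amp * k
  decoded <- decode_orientation(pop, state$W, config$readout,
                                config$angle_mapping)
  response <- NA_real_
  if (respond) {
    response <- wrap_orientation(decoded + stats::rnorm(1, 0, config$sigma))
    if (config$model == "two_process") {
      wj <- template_weights(response, config$alpha_w, config$beta_w,
                             config$offset, config$angle_mapping)
      state$W <- update_weights(state$W, wj, TRUE, config$w_decay)
    }
  }
  prof <- if (config$model == "gain") 1 + config$alpha_g * k
          else 1 - config$alpha_g * k
  state$amp <- if (config$adaptation_memory == "one_back") prof
  else (1 + (state$amp - 1) * (1 - config$memory_recovery)) * prof
  list(response = response, decoded = decoded, state = state)
}

#' Run a simulation over a trial table
#'
#' Generates model responses for every report trial of a trial table, one
#' independent state chain per subject. Rows whose `condition` is `"catch"`
#' are encoded (and drive gain/adaptation) but neither produce a response
#' nor update the decisional weights. If a `sequence_json` column is present
#' (sequence designs), every stimulus of the sequence is encoded in order —
#' each modulating the encoding of the next — and only the last one is
#' decoded and reported.
#'
#' @param trials Trial table with `subject`, `trial`, `stimulus`, optional
#'   `condition` and `sequence_json`.
#' @param config A [simulation_config()].
#' @param seed Random seed.
#' @return `trials` with `response` (and `decoded`) columns filled.
#' @export
run_simulation <- function(trials, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  trials <- trials[order(trials$subject, trials$trial), , drop = FALSE]
  n <- nrow(trials)
  has_cond <- "condition" %in% names(trials)
  has_seq <- "sequence_json" %in% names(trials) &&
    any(!is.na(trials$sequence_json) & nzchar(trials$sequence_json))
  seqs <- if (has_seq) lapply(trials$sequence_json, function(s) {
    if (is.na(s) || !nzchar(s)) NULL else jsonlite::fromJSON(s)
  }) else NULL

  K <- .kernel_table(config$beta, config$angle_mapping)
  prefs <- 0:179
  m <- if (config$angle_mapping == "double") 2 else 1
  sinp <- sin(.deg2rad(m * prefs)); cosp <- cos(.deg2rad(m * prefs))
  linear <- config$readout == "linear"
  two <- config$model == "two_process"
  gain <- config$model == "gain"
  one_back <- config$adaptation_memory == "one_back"
  recov <- config$memory_recovery
  noise <- stats::rnorm(n, 0, config$sigma)

  krow <- function(s) {
    si <- round(s) %% 180
    if (abs(s - round(s)) < 1e-9) K[si + 1L, ]
    else .channel_kernel(s, config$beta, config$angle_mapping)
  }
  decode <- function(eff) {
    if (linear) sum(eff * prefs) / sum(eff)
    else (atan2(sum(eff * sinp), sum(eff * cosp)) / m * 180 / pi) %% 180
  }

  response <- rep(NA_real_, n)
  decoded <- rep(NA_real_, n)
  subj <- as.character(trials$subject)
  amp <- rep(1, 180); W <- rep(1 / 180, 180)
  cur_subj <- NULL
  for (i in seq_len(n)) {
    if (!identical(subj[i], cur_subj)) {   # fresh chain per subject
      amp <- rep(1, 180); W <- rep(1 / 180, 180); cur_subj <- subj[i]
    }
    is_catch <- has_cond && identical(trials$condition[i], "catch")
    stim_list <- if (has_seq && !is.null(seqs[[i]])) seqs[[i]]
                 else trials$stimulus[i]
    nst <- length(stim_list)
    for (j in seq_len(nst)) {
      k <- krow(stim_list[j])
      last <- j == nst
      if (last && !is_catch) {
        eff <- amp * k * W
        dec <- decode(eff)
        decoded[i] <- dec
        response[i] <- (dec + noise[i]) %% 180
        if (two) {
          v <- config$offset + config$alpha_w *
            .channel_kernel(response[i], config$beta_w, config$angle_mapping)
          W <- W * config$w_decay + v / sum(v)
        }
      }
      prof <- if (gain) 1 + config$alpha_g * k else 1 - config$alpha_g * k
      amp <- if (one_back) prof else (1 + (amp - 1) * (1 - recov)) * prof
    }
  }
  trials$decoded <- decoded
  trials$response <- response
  trials
}

#' Convert tuning concentration to descriptive widths
#'
#' For the kernel `exp(beta * (cos(D) - 1))` reports, in orientation
#' degrees, the full width at half height and the circular SD, under either
#' angle mapping. No single width definition reproduces every quoted figure
#' in the literature; this helper makes the conversions explicit.
#'
#' @param beta Concentration parameter.
#' @param angle_mapping `"identity"` or `"double"`.
#' @return List with `fwhh` and `circular_sd`, both in degrees of
#'   orientation.
#' @export
#' @examples
#' beta_to_width(4.68)            # circular SD ~27.8 deg
#' beta_to_width(4.68, "double")  # FWHH ~31.6 deg
beta_to_width <- function(beta, angle_mapping = c("identity", "double")) {
  m <- if (match.arg(angle_mapping) == "double") 2 else 1
  fwhh <- 2 * acos(1 + log(0.5) / beta) * 180 / pi / m
  r <- besselI(beta, 1) / besselI(beta, 0)
  csd <- sqrt(-2 * log(r)) * 180 / pi / m
  list(fwhh = fwhh, circular_sd = csd)
}
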