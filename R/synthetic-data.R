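# Synthetic trial designs and behavior.
#
# Designs mirror the orientation-adjustment, sequence, contrast, ensemble
# and working-memory paradigms the analysis pipeline targets; behavior is
# generated from a known ground truth (DoG serial dependence, systematic
# stimulus-dependent biases, Gaussian response noise) so every downstream
# stage can be validated by parameter recovery.

.DESIGNS <- list(
  exp1 = list(n_subjects = 10, n_trials = 560, n_blocks = 4,
              orientation_grid = seq(0, 170, 10),
              delta_grid = seq(-50, 50, 10), catch_fraction = 0),
  exp2 = list(n_subjects = 10, n_trials = 440, n_blocks = 4,
              orientation_grid = 0:179,
              delta_grid = -80:80, catch_fraction = 0),
  exp3 = list(n_subjects = 15, n_trials = 600, n_blocks = 4,
              orientation_grid = seq(0, 165, 15),
              delta_grid = seq(-60, 60, 15), catch_fraction = 0.4),
  exp5 = list(n_subjects = 15, n_trials = 284, n_blocks = 4,
              orientation_grid = seq(0, 160, 20),
              delta_grid = seq(-80, 80, 20), catch_fraction = 0.2,
              sequence_length = 6),
  exp6 = list(n_subjects = 15, n_trials = 400, n_blocks = 5,
              orientation_grid = seq(0, 165, 15),
              delta_grid = seq(-60, 60, 15), catch_fraction = 0,
              contrast_levels = c(0.25, 0.75)),
  exp7 = list(n_subjects = 15, n_trials = 480, n_blocks = 4,
              size_levels = c(0.75, 0.945, 1.19, 1.5)),
  exp8 = list(n_subjects = 10, n_trials = 400, n_blocks = 4,
              size_levels = seq(0.5, 5, length.out = 50), n_items = 4)
)

#' Experiment design descriptor
#'
#' Returns the design parameters (orientation grid, consecutive-difference
#' grid, catch-trial fraction, sequence length, contrast/size levels, trial
#' counts) of one of the built-in experiment templates, optionally
#' overridden.
#'
#' @param experiment One of `"exp1"`, `"exp2"`, `"exp3"`, `"exp5"`,
#'   `"exp6"`, `"exp7"`, `"exp8"`:
#'   peripheral adjustment on a 10-degree grid; foveal adjustment with
#'   1-degree resolution; adjustment with 40% no-report catch trials;
#'   six-stimulus sequences with report of the last; contrast-varying
#'   adjustment; ensemble (mean-size) estimation; retro-cued size working
#'   memory.
#' @param n_subjects,n_trials Optional overrides of the per-template
#'   defaults (trials are per subject).
#' @param ... Further overrides of template fields (e.g. `catch_fraction`,
#'   `n_items`).
#' @return Object of class `experiment_design`.
#' @export
experiment_design <- function(experiment = c("exp1", "exp2", "exp3", "exp5",
                                             "exp6", "exp7", "exp8"),
                              n_subjects = NULL, n_trials = NULL, ...) {
  experiment <- match.arg(experiment)
  d <- .DESIGNS[[experiment]]
  d$experiment <- experiment
  if (!is.null(n_subjects)) d$n_subjects <- n_subjects
  if (!is.null(n_trials)) d$n_trials <- n_trials
  dots <- list(...)
  for (nm in names(dots)) d[[nm]] <- dots[[nm]]
  if (!is.null(d$orientation_grid)) {
    reach <- outer(d$orientation_grid, d$delta_grid, "-") %% 180
    if (!all(reach %in% d$orientation_grid))
      stop("delta grid is incompatible with the orientation grid: ",
           "stepping from a grid orientation by a grid delta must land on ",
           "the orientation grid")
  }
  structure(d, class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("Design", x$experiment, ":", x$n_subjects, "subjects x", x$n_trials,
      "trials\n")
  if (!is.null(x$orientation_grid))
    cat("  orientations {", paste(range(x$orientation_grid), collapse = ".."),
        "}, delta range +/-", max(x$delta_grid), "\n")
  if (!is.null(x$catch_fraction) && x$catch_fraction > 0)
    cat("  catch fraction", x$catch_fraction, "\n")
  invisible(x)
}

# constrained random walk on the orientation grid: every consecutive wrapped
# difference (previous minus present) lies exactly on the delta grid
.orientation_walk <- function(n, ogrid, dgrid) {
  s <- numeric(n)
  s[1] <- sample(ogrid, 1)
  d <- sample(dgrid, n - 1, replace = TRUE)
  for (i in 2:n) s[i] <- (s[i - 1] - d[i - 1]) %% 180
  s
}

#' Generate a trial design (stimuli only)
#'
#' Builds the per-subject stimulus sequences of the chosen design. For
#' orientation designs the sequence is a constrained random walk on the
#' orientation grid, so every wrapped consecutive difference lies exactly on
#' the declared delta grid. Catch trials (no-report) are assigned at the
#' declared fraction (exact count per subject, random positions). Sequence
#' designs store the full per-trial stimulus list as JSON
#' (`sequence_json`), with `stimulus` the last — to-be-reported — element;
#' their catch trials are truncated sequences. Size designs draw ensemble
#' mean sizes / item diameters from the declared levels
#' (`competitor_sizes_json` holds the non-target items).
#'
#' @param design An [experiment_design()] or an experiment id string.
#' @param seed Random seed (the whole table is reproducible from it).
#' @param ... Passed to [experiment_design()] when `design` is a string.
#' @return Trial table (data frame) with columns `subject`, `block`,
#'   `trial`, `experiment`, `stimulus`, `condition` (`"response"` or
#'   `"catch"`), plus design-specific columns (`contrast`, `sequence_json`,
#'   `competitor_sizes_json`). `response` and `rt_ms` are `NA` until
#'   behavior is generated.
#' @export
generate_design <- function(design, seed = 1, ...) {
  if (is.character(design)) design <- experiment_design(design, ...)
  set.seed(seed)
  d <- design
  per_subject <- function(subj) {
    n <- d$n_trials
    condition <- rep("response", n)
    if (!is.null(d$catch_fraction) && d$catch_fraction > 0) {
      n_catch <- round(d$catch_fraction * n)
      condition[sample(n, n_catch)] <- "catch"
    }
    tab <- data.frame(
      subject = subj,
      block = rep(seq_len(d$n_blocks %||% 1), each = ceiling(n / (d$n_blocks %||% 1)))[1:n],
      trial = seq_len(n),
      experiment = d$experiment,
      condition = condition,
      stringsAsFactors = FALSE
    )
    if (!is.null(d$sequence_length)) {
      # one continuous walk chopped into per-trial sequences
      L <- d$sequence_length
      walk <- .orientation_walk(n * L, d$orientation_grid, d$delta_grid)
      seqs <- split(walk, rep(seq_len(n), each = L))
      # catch trials end at a random position before the last stimulus
      seqs <- lapply(seq_len(n), function(i) {
        s <- seqs[[i]]
        if (condition[i] == "catch") s[seq_len(sample(L - 1, 1))] else s
      })
      tab$stimulus <- vapply(seqs, function(s) s[length(s)], numeric(1))
      tab$sequence_json <- vapply(seqs, function(s)
        as.character(jsonlite::toJSON(s, digits = NA)), character(1))
    } else if (!is.null(d$orientation_grid)) {
      tab$stimulus <- .orientation_walk(n, d$orientation_grid, d$delta_grid)
    } else if (d$experiment == "exp7") {
      tab$stimulus <- sample(d$size_levels, n, replace = TRUE)
    } else { # exp8
      n_items <- d$n_items %||% 4
      items <- matrix(sample(d$size_levels, n * n_items, replace = TRUE),
                      nrow = n)
      tab$stimulus <- items[, 1]
      tab$competitor_sizes_json <- apply(items[, -1, drop = FALSE], 1,
        function(s) as.character(jsonlite::toJSON(unname(s), digits = NA)))
    }
    if (!is.null(d$contrast_levels))
      tab$contrast <- sample(d$contrast_levels, n, replace = TRUE)
    tab
  }
  out <- do.call(rbind, lapply(sprintf("s%02d", seq_len(d$n_subjects)),
                               per_subject))
  out$response <- NA_real_
  out$rt_ms <- NA_real_
  rownames(out) <- NULL
  attr(out, "design") <- d
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ground truth for synthetic behavior
#'
#' Describes the generative process for [generate_behavior()]: a DoG serial
#' dependence of amplitude `alpha` (optionally varying across subjects with
#' SD `alpha_sd`) and width `w` on the chosen predictor, an optional
#' stimulus-dependent bias (sum of three sinusoids — the same family the
#' residualization fits, so removal can be exact), and Gaussian response
#' noise.
#'
#' @param alpha Group DoG amplitude in degrees (attraction > 0).
#' @param w DoG width parameter in `(0, 1)`.
#' @param alpha_sd Between-subject SD of the amplitude.
#' @param sigma Response noise SD in degrees (> 0).
#' @param predictor `"delta_S"` (bias follows the previous stimulus) or
#'   `"delta_R"` (follows the previous response; generated sequentially).
#' @param bias Optional orientation bias: a list with numeric vectors `a`
#'   (amplitudes, degrees), `b` (frequencies, cycles per normalized
#'   orientation unit) and `phase`, giving
#'   `sum_k a_k * sin(b_k * theta' + phase_k)` with
#'   `theta' = (theta - 90) / 51.96` (centered/scaled orientation).
#' @param rt_meanlog,rt_sdlog Log-normal reaction-time parameters (defaults
#'   give mean ~2.23 s, SD ~1.26 s).
#' @param rt_contaminant Fraction of trials receiving implausible RTs
#'   (fast guesses < 200 ms or extreme slow outliers), for filter testing.
#' @return Object of class `ground_truth`.
#' @export
ground_truth <- function(alpha = 2, w = 0.05, alpha_sd = 0, sigma = 10,
                         predictor = c("delta_S", "delta_R"), bias = NULL,
                         rt_meanlog = 0.664, rt_sdlog = 0.527,
                         rt_contaminant = 0) {
  stopifnot(sigma > 0, w > 0, w < 1)
  if (!is.null(bias))
    stopifnot(is.list(bias), length(bias$a) == length(bias$b),
              length(bias$b) == length(bias$phase))
  structure(list(alpha = alpha, w = w, alpha_sd = alpha_sd, sigma = sigma,
                 predictor = match.arg(predictor), bias = bias,
                 rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog,
                 rt_contaminant = rt_contaminant),
            class = "ground_truth")
}

#' Default three-sinusoid orientation bias
#'
#' A convenient systematic response bias in the family the residualization
#' model fits: repulsion-like shifts varying smoothly over the orientation
#' range.
#'
#' @param scale Overall amplitude multiplier in degrees.
#' @return Bias list for [ground_truth()].
#' @export
orientation_bias_default <- function(scale = 1) {
  list(a = scale * c(2.0, 1.0, 0.6),
       b = c(1.8, 3.6, 5.4),
       phase = c(0.4, 1.1, 2.3))
}

.eval_bias <- function(bias, theta) {
  if (is.null(bias)) return(0 * theta)
  tn <- (theta - 90) / 51.96
  out <- 0
  for (k in seq_along(bias$a))
    out <- out + bias$a[k] * sin(bias$b[k] * tn + bias$phase[k])
  out
}

.gen_rt <- function(n, truth) {
  rt <- stats::rlnorm(n, truth$rt_meanlog, truth$rt_sdlog) * 1000
  if (truth$rt_contaminant > 0) {
    bad <- which(stats::runif(n) < truth$rt_contaminant)
    fast <- bad[seq_len(ceiling(length(bad) / 2))]
    slow <- setdiff(bad, fast)
    rt[fast] <- stats::runif(length(fast), 50, 190)
    rt[slow] <- stats::runif(length(slow), 15000, 30000)
  }
  rt
}

#' Generate synthetic adjustment behavior
#'
#' Fills the `response` and `rt_ms` columns of an orientation design:
#' `response = stimulus + DoG(predictor; alpha_i, w) + bias(stimulus) +
#' noise`, wrapped to `[0, 180)`. With `predictor = "delta_R"` responses are
#' generated sequentially, each feeding the next trial's predictor. Catch
#' trials get no response; they still act as the "previous stimulus" of the
#' following trial.
#'
#' @param trials Trial table from [generate_design()].
#' @param truth A [ground_truth()].
#' @param seed Random seed.
#' @return The trial table with `response` and `rt_ms` filled (and the
#'   per-subject true amplitudes in `attr(, "alpha_subject")`).
#' @export
generate_behavior <- function(trials, truth = ground_truth(), seed = 1) {
  set.seed(seed)
  trials <- trials[order(trials$subject, trials$trial), , drop = FALSE]
  subjects <- unique(trials$subject)
  alpha_i <- truth$alpha + stats::rnorm(length(subjects), 0, truth$alpha_sd)
  names(alpha_i) <- subjects
  n <- nrow(trials)
  noise <- stats::rnorm(n, 0, truth$sigma)
  bias <- .eval_bias(truth$bias, trials$stimulus)
  is_catch <- if ("condition" %in% names(trials))
    trials$condition == "catch" else rep(FALSE, n)
  response <- rep(NA_real_, n)
  subj <- as.character(trials$subject)

  if (truth$predictor == "delta_S") {
    prev_stim <- c(NA, trials$stimulus[-n])
    prev_stim[c(TRUE, subj[-1] != subj[-n])] <- NA
    ds <- wrap_delta(prev_stim, trials$stimulus)
    sd_term <- ifelse(is.na(ds), 0, dog(ds, 1, truth$w)) * alpha_i[subj]
    response <- wrap_orientation(trials$stimulus + sd_term + bias + noise)
  } else {
    prev_resp <- NA_real_
    cur <- ""
    for (i in seq_len(n)) {
      if (subj[i] != cur) { prev_resp <- NA_real_; cur <- subj[i] }
      dr <- if (is.na(prev_resp)) NA_real_
            else wrap_delta(prev_resp, trials$stimulus[i])
      sd_term <- if (is.na(dr)) 0 else dog(dr, alpha_i[subj[i]], truth$w)
      r <- wrap_orientation(trials$stimulus[i] + sd_term + bias[i] + noise[i])
      if (!is_catch[i]) { response[i] <- r; prev_resp <- r }
      # on catch trials nothing is reported; the predictor chain keeps the
      # last actual report
    }
  }
  response[is_catch] <- NA_real_
  trials$response <- response
  trials$rt_ms <- .gen_rt(n, truth)
  trials$rt_ms[is_catch] <- NA_real_
  attr(trials, "alpha_subject") <- alpha_i
  trials
}

#' Generate synthetic size-estimation behavior
#'
#' For ensemble (mean-size) and retro-cue working-memory designs: the
#' reported size is `intercept + bias_slope * stimulus` plus configurable
#' linear history terms (previous-stimulus `delta_S`, previous-response
#' `delta_R`, competitor `delta_C` differences) plus Gaussian noise. A
#' `bias_slope` different from 1 injects the central-tendency /
#' edge-overshoot biases the size residualization must remove.
#'
#' @param trials Trial table from [generate_design()] (`exp7` or `exp8`).
#' @param slopes Named list of history slopes: `delta_S`, `delta_R`,
#'   `delta_C` (scalar, or vector for multiple competitors ordered nearest
#'   first).
#' @param bias_slope Slope of report vs. true size (1 = unbiased).
#' @param intercept Constant report offset.
#' @param sigma Response noise SD (same units as sizes).
#' @param seed Random seed.
#' @return Trial table with `response` and `rt_ms` filled.
#' @export
generate_size_behavior <- function(trials,
                                   slopes = list(delta_S = 0, delta_R = 0,
                                                 delta_C = 0),
                                   bias_slope = 1, intercept = 0,
                                   sigma = 0.25, seed = 1) {
  set.seed(seed)
  trials <- trials[order(trials$subject, trials$trial), , drop = FALSE]
  n <- nrow(trials)
  subj <- as.character(trials$subject)
  noise <- stats::rnorm(n, 0, sigma)
  comp <- if ("competitor_sizes_json" %in% names(trials))
    lapply(trials$competitor_sizes_json, jsonlite::fromJSON) else NULL
  bS <- slopes$delta_S %||% 0
  bR <- slopes$delta_R %||% 0
  bC <- slopes$delta_C %||% 0
  response <- numeric(n)
  prev_stim <- NA_real_; prev_resp <- NA_real_; cur <- ""
  for (i in seq_len(n)) {
    if (subj[i] != cur) { prev_stim <- NA_real_; prev_resp <- NA_real_
      cur <- subj[i] }
    s <- trials$stimulus[i]
    hist_term <- 0
    if (!is.na(prev_stim)) hist_term <- hist_term + bS * (prev_stim - s)
    if (!is.na(prev_resp)) hist_term <- hist_term + bR * (prev_resp - s)
    if (!is.null(comp)) {
      dc <- comp[[i]] - s
      bC_i <- rep_len(bC, length(dc))
      hist_term <- hist_term + sum(bC_i * dc)
    }
    r <- intercept + bias_slope * s + hist_term + noise[i]
    response[i] <- max(r, 0.01)
    prev_stim <- s; prev_resp <- response[i]
  }
  trials$response <- response
  trials$rt_ms <- stats::rlnorm(n, 0.664, 0.527) * 1000
  trials
}
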