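# Data conditioning before model fitting: reaction-time filters, demeaning,
# Grubbs outlier exclusion, and residualization of stimulus-dependent
# response biases (sinusoidal for orientation, linear for size).

#' Filter trials on reaction times
#'
#' Removes trials with unrealistically fast (`< rt_min` ms) or outlier
#' (`|z| > z_max`, z-scored per subject) reaction times, *and the trial
#' immediately following each removed trial* (whose "previous response" is
#' unreliable). Catch trials (no RT) are never themselves flagged.
#'
#' @param data Trial table with `rt_ms`.
#' @param rt_min Fast-guess threshold in ms.
#' @param z_max Outlier threshold in per-subject SD units.
#' @return List with `data` (filtered table) and `report` (counts and
#'   fraction removed).
#' @export
filter_trials <- function(data, rt_min = 200, z_max = 3.5) {
  stopifnot("rt_ms" %in% names(data))
  data <- data[order(data$subject, data$trial), , drop = FALSE]
  rt <- data$rt_ms
  subj <- as.character(data$subject)
  mu <- stats::ave(rt, subj, FUN = function(v) mean(v, na.rm = TRUE))
  sdv <- stats::ave(rt, subj, FUN = function(v) stats::sd(v, na.rm = TRUE))
  z <- (rt - mu) / ifelse(sdv > 0, sdv, Inf)
  bad <- !is.na(rt) & (rt < rt_min | abs(z) > z_max)
  foll <- c(FALSE, bad[-length(bad)]) & subj == c(NA, subj[-length(subj)])
  foll[is.na(foll)] <- FALSE
  drop <- bad | foll
  if (all(drop)) stop("reaction-time filter removed every trial")
  list(data = data[!drop, , drop = FALSE],
       report = list(n_removed_rt = sum(bad),
                     n_removed_following = sum(foll & !bad),
                     fraction_removed = mean(drop)))
}

#' Critical value of the two-sided Grubbs test
#'
#' @param n Sample size.
#' @param alpha Significance level.
#' @return Critical value for `max |x - mean| / sd`.
#' @export
grubbs_critical <- function(n, alpha = 0.05) {
  t <- stats::qt(1 - alpha / (2 * n), n - 2)
  (n - 1) / sqrt(n) * sqrt(t^2 / (n - 2 + t^2))
}

#' Iterative two-sided Grubbs outlier filter
#'
#' Repeatedly removes the single most extreme observation while its Grubbs
#' statistic exceeds the critical value. With fewer than 3 observations or
#' zero variance nothing is removed.
#'
#' @param x Numeric vector.
#' @param alpha Significance level per iteration.
#' @return Logical vector, `TRUE` for kept observations; attribute
#'   `n_removed` gives the removal count.
#' @export
grubbs_filter <- function(x, alpha = 0.05) {
  keep <- !is.na(x)
  if (sum(keep) < 3) {
    warning("fewer than 3 observations: Grubbs filter is a pass-through")
    return(structure(keep | is.na(x), n_removed = 0L))
  }
  active <- which(keep)
  repeat {
    v <- x[active]
    n <- length(v)
    if (n < 3) break
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) break
    dev <- abs(v - mean(v))
    i <- which.max(dev)
    if (dev[i] / s > grubbs_critical(n, alpha)) active <- active[-i]
    else break
  }
  out <- rep(FALSE, length(x))
  out[active] <- TRUE
  out[is.na(x)] <- TRUE  # NA rows (e.g. catch trials) are not judged
  structure(out, n_removed = sum(!is.na(x)) - length(active))
}

# fit the three-sinusoid bias model for one subject
.fit_sinusoid <- function(theta, err, n_sin = 3, downweight_sd = 3,
                          downweight_to = 0.1) {
  tn <- (theta - mean(theta)) / stats::sd(theta)
  wts <- rep(1, length(err))
  out <- abs(err - mean(err)) > downweight_sd * stats::sd(err)
  wts[out] <- downweight_to
  # frequency starts from the dominant discrete-Fourier components of the
  # binned mean error over orientation
  br <- seq(min(theta), max(theta) + 1, length.out = 37)
  bm <- tapply(err, cut(theta, br, include.lowest = TRUE),
               mean, na.rm = TRUE)
  bm[is.na(bm)] <- 0
  sp <- Mod(stats::fft(as.vector(bm)))[2:12]
  top <- order(sp, decreasing = TRUE)[seq_len(n_sin)]
  # convert cycles-over-range to angular frequency in tn units
  span <- diff(range(tn))
  b0 <- sort(2 * pi * top / span)
  df <- data.frame(tn = tn, err = err)
  start <- list()
  for (k in seq_len(n_sin)) {
    start[[paste0("a", k)]] <- stats::sd(err) / k
    start[[paste0("b", k)]] <- b0[k]
    start[[paste0("p", k)]] <- 0
  }
  form <- stats::as.formula(paste("err ~",
    paste(sprintf("a%d * sin(b%d * tn + p%d)", 1:n_sin, 1:n_sin, 1:n_sin),
          collapse = " + ")))
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = df, start = start, weights = wts,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # fall back to the fourth-degree polynomial comparison model
    pf <- stats::lm(err ~ poly(tn, 4), weights = wts)
    return(list(predict = function(theta_new) {
      tnn <- (theta_new - mean(theta)) / stats::sd(theta)
      stats::predict(pf, data.frame(tn = tnn))
    }, family = "poly4", coef = stats::coef(pf),
    rms = sqrt(mean(stats::residuals(pf)^2))))
  }
  list(predict = function(theta_new) {
    tnn <- (theta_new - mean(theta)) / stats::sd(theta)
    stats::predict(fit, data.frame(tn = tnn))
  }, family = "sin3", coef = stats::coef(fit),
  rms = sqrt(mean(stats::residuals(fit)^2)))
}

#' Remove stimulus-dependent orientation biases
#'
#' Orientation reports carry systematic, stimulus-locked biases (e.g.
#' repulsion from cardinal axes) that masquerade as serial dependence on the
#' previous *response*. Per subject, the mean error as a function of
#' stimulus orientation is fitted with a sum of `n_sin` sinusoids of the
#' centered/scaled orientation (robustly: points beyond `downweight_sd` SD
#' of the error mean get weight `downweight_to`), and the fitted curve is
#' subtracted. Responses are updated to `stimulus + residual error`, so all
#' downstream predictors (including delta-R) use bias-free reports. Falls
#' back to a fourth-degree polynomial for a subject if the sinusoid fit
#' fails to converge.
#'
#' @param data Trial table.
#' @param n_sin Number of sinusoids.
#' @param downweight_sd,downweight_to Robustness parameters.
#' @return List with `data` (bias-corrected table) and `fits` (per-subject
#'   fit info: family, coefficients, residual rms).
#' @export
residualize_orientation_bias <- function(data, n_sin = 3, downweight_sd = 3,
                                         downweight_to = 0.1) {
  data <- data[order(data$subject, data$trial), , drop = FALSE]
  err <- wrap_delta(data$response, data$stimulus)
  fits <- list()
  for (s in unique(data$subject)) {
    i <- which(data$subject == s & !is.na(err))
    if (length(i) < 30) next
    f <- .fit_sinusoid(data$stimulus[i], err[i], n_sin,
                       downweight_sd, downweight_to)
    fits[[as.character(s)]] <- f[c("family", "coef", "rms")]
    err[i] <- err[i] - f$predict(data$stimulus[i])
  }
  ok <- !is.na(err)
  data$response[ok] <- wrap_orientation(data$stimulus[ok] + err[ok])
  list(data = data, fits = fits)
}

#' Remove linear size-report biases
#'
#' Size reports show central-tendency (slope < 1) or edge-overshoot
#' (slope > 1) distortions. Per subject, the error (report minus true size)
#' is regressed linearly on the true size and the fitted line subtracted,
#' after which the report-vs-truth slope is 1 by construction.
#'
#' @param data Size-task trial table (`stimulus`, `response` in size units).
#' @return List with `data` (corrected) and `fits` (per-subject intercept
#'   and slope removed).
#' @export
residualize_size_bias <- function(data) {
  data <- data[order(data$subject, data$trial), , drop = FALSE]
  err <- data$response - data$stimulus
  fits <- list()
  for (s in unique(data$subject)) {
    i <- which(data$subject == s & !is.na(err))
    if (length(i) < 3) next
    f <- stats::lm(err[i] ~ data$stimulus[i])
    fits[[as.character(s)]] <- stats::coef(f)
    err[i] <- stats::residuals(f)
  }
  ok <- !is.na(err)
  data$response[ok] <- data$stimulus[ok] + err[ok]
  list(data = data, fits = fits)
}

#' Empirical chance-performance test
#'
#' For each subject, compares the observed mean absolute error against a
#' null in which each response is paired with the correct answer of a
#' randomly chosen trial (`n_perm` pairings). Subjects performing at chance
#' get large p; genuine task performance gives `p ~ 1/n_perm`.
#'
#' @param data Trial table.
#' @param n_perm Number of random pairings.
#' @param circular Treat errors as circular orientation differences
#'   (otherwise plain differences, for size tasks).
#' @param seed Random seed.
#' @return Named vector of per-subject p-values (add-one corrected).
#' @export
chance_performance_test <- function(data, n_perm = 10000, circular = TRUE,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  errfun <- if (circular) function(r, s) abs(wrap_delta(r, s))
            else function(r, s) abs(r - s)
  subjects <- unique(data$subject)
  out <- vapply(subjects, function(su) {
    i <- data$subject == su & !is.na(data$response)
    r <- data$response[i]; s <- data$stimulus[i]
    obs <- mean(errfun(r, s))
    null <- vapply(seq_len(n_perm), function(b)
      mean(errfun(r, sample(s))), numeric(1))
    (1 + sum(null <= obs)) / (n_perm + 1)
  }, numeric(1))
  names(out) <- as.character(subjects)
  out
}

#' Standard preprocessing pipeline for adjustment data
#'
#' Applies, in order: the reaction-time filter, per-subject demeaning of the
#' (circular) errors, the per-subject iterative Grubbs filter on the
#' demeaned errors, and (optionally) orientation-bias residualization.
#' Errors are the wrapped difference between response and stimulus
#' throughout, so they are bounded to +/-90 degrees by construction.
#'
#' @param data Trial table.
#' @param residualize Apply [residualize_orientation_bias()]?
#' @param rt_filter Apply [filter_trials()]?
#' @param grubbs_alpha Significance level of the Grubbs step.
#' @return List with `data` (clean table) and `report` (class
#'   `cleaning_report`: removal counts, fraction removed, per-subject mean
#'   error removed by demeaning, residualization fit summaries).
#' @export
preprocess_trials <- function(data, residualize = TRUE, rt_filter = TRUE,
                              grubbs_alpha = 0.05) {
  report <- list()
  if (rt_filter && "rt_ms" %in% names(data) && any(!is.na(data$rt_ms))) {
    ft <- filter_trials(data)
    data <- ft$data
    report <- ft$report
  } else {
    report <- list(n_removed_rt = 0L, n_removed_following = 0L,
                   fraction_removed = 0)
  }
  n0 <- nrow(data)
  err <- wrap_delta(data$response, data$stimulus)
  mu <- tapply(err, data$subject, mean, na.rm = TRUE)
  report$per_subject_mean_error <- mu
  err <- err - mu[as.character(data$subject)]
  keep <- rep(TRUE, nrow(data))
  nrem <- 0L
  for (s in unique(data$subject)) {
    i <- which(data$subject == s)
    k <- grubbs_filter(err[i], alpha = grubbs_alpha)
    keep[i] <- k
    nrem <- nrem + attr(k, "n_removed")
  }
  report$n_removed_grubbs <- nrem
  ok <- !is.na(err)
  data$response[ok] <- wrap_orientation(data$stimulus[ok] + err[ok])
  data <- data[keep, , drop = FALSE]
  if (residualize) {
    rb <- residualize_orientation_bias(data)
    data <- rb$data
    report$residualization <- rb$fits
  }
  report$fraction_removed_total <- 1 - nrow(data) / max(1, n0) +
    report$fraction_removed
  list(data = data, report = structure(report, class = "cleaning_report"))
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("Cleaning report:\n")
  cat(sprintf("  RT filter: %d fast/outlier + %d following (%.2f%% of trials)\n",
              x$n_removed_rt, x$n_removed_following,
              100 * x$fraction_removed))
  cat(sprintf("  Grubbs: %d removed; total removed %.2f%%\n",
              x$n_removed_grubbs, 100 * x$fraction_removed_total))
  if (!is.null(x$residualization))
    cat("  residualization:", length(x$residualization), "subject fits\n")
  invisible(x)
}
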