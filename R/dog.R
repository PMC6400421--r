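# Derivative-of-Gaussian (DoG) serial-dependence model and its fitters.
#
# The response-error curve is y = x * alpha * w * c * exp(-(w x)^2) with
# c = sqrt(2) * exp(0.5), the unique constant for which alpha equals the
# height of the curve's peak (and valley). The peak sits at x = 1/(w sqrt(2)).
# Fitting exploits that the model is linear in alpha given w: the likelihood
# is profiled over w (and over the random-amplitude variance ratio), solving
# a closed-form linear mixed model at each candidate width.

C_DOG <- sqrt(2) * exp(0.5)

#' Derivative-of-Gaussian serial-dependence curve
#'
#' @param x Predictor in degrees (previous minus current stimulus or
#'   response), typically in `(-90, 90]`.
#' @param alpha Amplitude in degrees: the height of the peak (positive =
#'   attraction toward the previous stimulus/response, negative = repulsion).
#' @param w Inverse-width parameter in 1/degrees, in `(0, 1)`; the peak lies
#'   at `1/(w*sqrt(2))` degrees.
#' @return Predicted error in degrees.
#' @export
#' @examples
#' dog(seq(-90, 90, 10), alpha = 2, w = 0.05)
#' dog(dog_peak(0.05), alpha = 2, w = 0.05)  # exactly 2
dog <- function(x, alpha, w) {
  x * alpha * w * C_DOG * exp(-(w * x)^2)
}

#' Peak location of the DoG curve
#'
#' @param w Inverse-width parameter in 1/degrees.
#' @return Location of the curve maximum in degrees, `1/(w*sqrt(2))`.
#' @export
dog_peak <- function(w) 1 / (w * sqrt(2))

# unit-amplitude basis
.dog_basis <- function(x, w) x * w * C_DOG * exp(-(w * x)^2)

#' Add serial-dependence predictors to a trial table
#'
#' Computes, within each subject and in trial order, the wrapped difference
#' between the previous trial's stimulus (`delta_S`) or response (`delta_R`)
#' and the current stimulus. With `future = TRUE` the *next* trial's
#' stimulus/response is used instead, which is the causality control: a true
#' serial dependence cannot act backwards in time. Also records the previous
#' trial's condition flag (`prev_condition`), used e.g. to split trials by
#' whether the preceding trial required a response.
#'
#' @param data Trial table with columns `subject`, `trial`, `stimulus`,
#'   `response` (orientations in degrees).
#' @param future Logical; use trial n+1 instead of n-1 as the reference.
#' @return `data` with columns `delta_S`, `delta_R`, `prev_condition` added.
#'   The first (or last, if `future`) trial of each subject gets `NA`.
#' @export
serial_predictors <- function(data, future = FALSE) {
  stopifnot(all(c("subject", "trial", "stimulus", "response") %in% names(data)))
  data <- data[order(data$subject, data$trial), , drop = FALSE]
  shift <- function(v, subj) {
    n <- length(v)
    out <- rep(NA, n)
    if (future) {
      out[-n] <- v[-1]
      out[-n][subj[-n] != subj[-1]] <- NA
    } else {
      out[-1] <- v[-n]
      out[-1][subj[-1] != subj[-n]] <- NA
    }
    out
  }
  subj <- as.character(data$subject)
  prev_stim <- shift(data$stimulus, subj)
  prev_resp <- shift(data$response, subj)
  data$delta_S <- wrap_delta(prev_stim, data$stimulus)
  data$delta_R <- wrap_delta(prev_resp, data$stimulus)
  if ("condition" %in% names(data)) {
    data$prev_condition <- shift(as.character(data$condition), subj)
  }
  data
}

# error in degrees, circular
.circ_error <- function(data) wrap_delta(data$response, data$stimulus)

# rows usable for a given predictor
.fit_frame <- function(data, predictor) {
  predictor <- match.arg(predictor, c("delta_S", "delta_R"))
  if (!predictor %in% names(data)) data <- serial_predictors(data)
  y <- .circ_error(data)
  x <- data[[predictor]]
  keep <- !is.na(x) & !is.na(y)
  list(y = y[keep], x = x[keep], subject = as.character(data$subject)[keep])
}

# ---- closed-form profile ML for the random-amplitude model ------------------
#
# y_ij = g(x_ij; w) * (alpha0 + u_i) + e_ij,  u_i ~ N(0, su^2), e ~ N(0, se^2)
# With lambda = su^2/se^2 the per-subject covariance is se^2 (I + lambda gg'),
# so GLS, the profiled residual sum Q and the determinant are all closed form
# (Woodbury); only w and lambda need numeric optimization.

.ml_suff <- function(y, g, subject) {
  s <- rowsum(g * g, subject, reorder = TRUE)
  t <- rowsum(g * y, subject, reorder = TRUE)
  q <- rowsum(y * y, subject, reorder = TRUE)
  list(s = as.vector(s), t = as.vector(t), q = as.vector(q),
       N = length(y), subjects = rownames(s))
}

.ml_neg2ll <- function(lambda, st) {
  den <- 1 + lambda * st$s
  sw <- sum(st$s / den)
  if (sw <= 0) return(Inf)
  a0 <- sum(st$t / den) / sw
  Q <- sum(st$q - 2 * a0 * st$t + a0^2 * st$s -
             lambda * (st$t - a0 * st$s)^2 / den)
  if (Q <= 0) return(Inf)
  st$N * log(2 * pi * Q / st$N) + st$N + sum(log(den))
}

.ml_profile_lambda <- function(st, upper = 1e3) {
  opt <- stats::optimize(.ml_neg2ll, c(0, upper), st = st, tol = 1e-8)
  at0 <- .ml_neg2ll(0, st)
  if (at0 <= opt$objective) list(lambda = 0, neg2ll = at0)
  else list(lambda = opt$minimum, neg2ll = opt$objective)
}

# profile neg2ll as a function of w only
.ml_profile_w <- function(w, y, x, subject) {
  g <- .dog_basis(x, w)
  .ml_profile_lambda(.ml_suff(y, g, subject))$neg2ll
}

# neg2ll at fixed (alpha0, w), with lambda and sigma_e profiled out; used
# for the joint profile-likelihood Hessian of (alpha0, w)
.ml_fixed_neg2ll <- function(alpha0, w, y, x, subject) {
  st <- .ml_suff(y, .dog_basis(x, w), subject)
  f <- function(lambda) {
    den <- 1 + lambda * st$s
    Q <- sum(st$q - 2 * alpha0 * st$t + alpha0^2 * st$s -
               lambda * (st$t - alpha0 * st$s)^2 / den)
    if (Q <= 0) return(Inf)
    st$N * log(2 * pi * Q / st$N) + st$N + sum(log(den))
  }
  opt <- stats::optimize(f, c(0, 1e3), tol = 1e-8)
  min(f(0), opt$objective)
}

# Wald SE of alpha0 from the curvature of the 2-D (alpha0, w) profile
# likelihood. When w is estimated, the amplitude's conditional-on-w SE is
# anticonservative (the width search inflates |z| under the null); the
# joint profile curvature restores calibration.
.ml_joint_se <- function(alpha0, w, y, x, subject, se_cond) {
  h_a <- max(abs(alpha0) * 1e-3, 0.05)
  h_w <- max(w * 5e-3, 5e-4)
  f <- function(a, ww) .ml_fixed_neg2ll(a, ww, y, x, subject)
  f0 <- f(alpha0, w)
  H <- matrix(0, 2, 2)
  H[1, 1] <- (f(alpha0 + h_a, w) - 2 * f0 + f(alpha0 - h_a, w)) / h_a^2
  H[2, 2] <- (f(alpha0, w + h_w) - 2 * f0 + f(alpha0, w - h_w)) / h_w^2
  H[1, 2] <- H[2, 1] <-
    (f(alpha0 + h_a, w + h_w) - f(alpha0 + h_a, w - h_w) -
       f(alpha0 - h_a, w + h_w) + f(alpha0 - h_a, w - h_w)) /
    (4 * h_a * h_w)
  V <- tryCatch(2 * solve(H), error = function(e) NULL)
  if (is.null(V) || !is.finite(V[1, 1]) || V[1, 1] <= 0) return(se_cond)
  max(sqrt(V[1, 1]), se_cond)
}

#' Fit the multilevel DoG model of serial dependence
#'
#' Fits trial-wise adjustment errors with a DoG of the chosen predictor, with
#' a group-level fixed amplitude `alpha0`, a subject-level random amplitude
#' deviation, and a single shared width `w`. Estimation is exact profile
#' maximum likelihood: for fixed `w` (and variance ratio) the model is a
#' closed-form linear mixed model, so the likelihood is profiled over `w` on
#' `(0, 1)` (grid pass, then local refinement). Significance of `alpha0` is a
#' z-test (estimate over standard error, standard normal reference). When
#' `w` is estimated, the standard error comes from the curvature of the
#' joint `(alpha0, w)` profile likelihood — the conditional-on-w SE would be
#' anticonservative, because searching the width inflates the amplitude
#' z-statistic under the null. For the same reason, the default `p` of a
#' free-width fit is a likelihood-ratio test against the no-dependence null
#' (pure noise), referred to chi-squared with 3 df (`alpha0`, `w` and the
#' random-amplitude variance all exist only under the alternative); the
#' z-based p is kept in `p_z`. With `fix_w` given, `p` is the plain z-test.
#'
#' @param data Trial table (see [serial_predictors()]); errors are the
#'   wrapped circular difference response minus stimulus.
#' @param predictor `"delta_S"` (previous stimulus) or `"delta_R"` (previous
#'   response).
#' @param fix_w Optional fixed width; if given, only the amplitude structure
#'   is estimated.
#' @param w_bounds Search interval for `w`.
#' @return Object of class `dog_fit`: amplitude `alpha0` with `se`, `z`, `p`;
#'   width `w`; `peak` location; per-subject amplitudes (`alpha_subject`,
#'   BLUPs); variance components; `rmse` of conditional residuals; `loglik`,
#'   `aic`, and pointwise log-likelihood (for model comparison).
#' @export
fit_multilevel_dog <- function(data, predictor = c("delta_S", "delta_R"),
                               fix_w = NULL, w_bounds = c(0.005, 0.995)) {
  predictor <- match.arg(predictor)
  fr <- .fit_frame(data, predictor)
  if (length(unique(fr$subject)) < 2)
    stop("multilevel fit needs at least 2 subjects; use fit_dog() for one")
  if (length(fr$y) < 10) stop("too few usable trials")

  if (is.null(fix_w)) {
    grid <- exp(seq(log(w_bounds[1]), log(w_bounds[2]), length.out = 40))
    prof <- vapply(grid, .ml_profile_w, numeric(1),
                   y = fr$y, x = fr$x, subject = fr$subject)
    i <- which.min(prof)
    lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
    opt <- stats::optimize(.ml_profile_w, c(lo, hi), y = fr$y, x = fr$x,
                           subject = fr$subject, tol = 1e-7)
    w <- opt$minimum
  } else {
    w <- fix_w
  }

  g <- .dog_basis(fr$x, w)
  st <- .ml_suff(fr$y, g, fr$subject)
  pl <- .ml_profile_lambda(st)
  lambda <- pl$lambda
  den <- 1 + lambda * st$s
  alpha0 <- sum(st$t / den) / sum(st$s / den)
  Q <- sum(st$q - 2 * alpha0 * st$t + alpha0^2 * st$s -
             lambda * (st$t - alpha0 * st$s)^2 / den)
  sigma_e <- sqrt(Q / st$N)
  sigma_u <- sqrt(lambda) * sigma_e
  se <- sigma_e / sqrt(sum(st$s / den))
  if (is.null(fix_w))
    se <- .ml_joint_se(alpha0, w, fr$y, fr$x, fr$subject, se)
  u <- lambda * (st$t - alpha0 * st$s) / den
  names(u) <- st$subjects
  fitted <- (alpha0 + u[fr$subject]) * g
  resid <- fr$y - fitted
  ll_i <- stats::dnorm(fr$y, fitted, sigma_e, log = TRUE)
  n_par <- if (is.null(fix_w)) 4 else 3
  loglik <- -pl$neg2ll / 2
  z <- alpha0 / se
  p_z <- 2 * stats::pnorm(-abs(z))
  # null model: no serial dependence at all (alpha0, w and the random
  # amplitude all vanish), so the free-width fit is referred to chi-sq(3);
  # this keeps the test calibrated despite the width search
  neg2ll_null <- st$N * log(2 * pi * mean(fr$y^2)) + st$N
  lrt <- neg2ll_null - pl$neg2ll
  p <- if (is.null(fix_w))
    stats::pchisq(lrt, df = 3, lower.tail = FALSE) else p_z
  structure(list(
    predictor = predictor, alpha0 = alpha0, se_alpha0 = se,
    z = z, p = p, p_z = p_z, lrt_null = lrt,
    w = w, peak = dog_peak(w),
    alpha_subject = alpha0 + u, u = u,
    sigma_e = sigma_e, sigma_u = sigma_u, lambda = lambda,
    rmse = sqrt(mean(resid^2)), loglik = loglik,
    aic = 2 * n_par - 2 * loglik, n_par = n_par,
    n = st$N, n_subjects = length(st$s),
    fitted = fitted, residuals = resid, pointwise_ll = ll_i,
    x = fr$x, y = fr$y, subject = fr$subject
  ), class = "dog_fit")
}

#' Fit a single-level DoG curve
#'
#' Ordinary least-squares DoG fit for a single error series (e.g. one
#' simulated observer): amplitude is closed-form given `w`; `w` is profiled
#' unless fixed. Used by the simulator calibration sweeps, where the
#' amplitude at a fixed reference width (default free) characterizes the
#' bias magnitude.
#'
#' @param x Predictor values in degrees.
#' @param y Errors in degrees.
#' @param fix_w Optional fixed width.
#' @param w_bounds Search interval for free `w`.
#' @return Object of class `dog_fit` (single-level flavor: no random effects).
#' @export
fit_dog <- function(x, y, fix_w = NULL, w_bounds = c(0.005, 0.995)) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  sse_w <- function(w) {
    g <- .dog_basis(x, w)
    a <- sum(g * y) / sum(g * g)
    sum((y - a * g)^2)
  }
  if (is.null(fix_w)) {
    grid <- exp(seq(log(w_bounds[1]), log(w_bounds[2]), length.out = 40))
    prof <- vapply(grid, sse_w, numeric(1))
    i <- which.min(prof)
    opt <- stats::optimize(sse_w, c(grid[max(1, i - 1)],
                                    grid[min(length(grid), i + 1)]), tol = 1e-7)
    w <- opt$minimum
  } else w <- fix_w
  g <- .dog_basis(x, w)
  alpha <- sum(g * y) / sum(g * g)
  resid <- y - alpha * g
  n <- length(y)
  n_par <- if (is.null(fix_w)) 2 else 1
  sigma <- sqrt(sum(resid^2) / max(1, n - n_par))
  se <- sigma / sqrt(sum(g * g))
  z <- alpha / se
  sigma_ml <- sqrt(mean(resid^2))
  ll <- sum(stats::dnorm(y, alpha * g, sigma_ml, log = TRUE))
  structure(list(
    predictor = NA_character_, alpha0 = alpha, se_alpha0 = se,
    z = z, p = 2 * stats::pnorm(-abs(z)),
    w = w, peak = dog_peak(w),
    alpha_subject = NULL, sigma_e = sigma, sigma_u = 0, lambda = 0,
    rmse = sqrt(mean(resid^2)), loglik = ll,
    aic = 2 * (n_par + 1) - 2 * ll, n_par = n_par,
    n = n, n_subjects = 1,
    fitted = alpha * g, residuals = resid,
    pointwise_ll = stats::dnorm(y, alpha * g, sigma_ml, log = TRUE),
    x = x, y = y, subject = rep("1", n)
  ), class = "dog_fit")
}

#' @export
print.dog_fit <- function(x, ...) {
  cat("DoG fit", if (!is.na(x$predictor)) paste0("(", x$predictor, ")"), "\n")
  cat(sprintf("  alpha0 = %.3f deg (SE %.3f), z = %.2f, p = %.3g\n",
              x$alpha0, x$se_alpha0, x$z, x$p))
  cat(sprintf("  w = %.4f (peak at %.1f deg), sigma_e = %.2f, sigma_u = %.2f\n",
              x$w, x$peak, x$sigma_e, x$sigma_u))
  cat(sprintf("  n = %d trials, %d subject(s), rmse = %.3f, AIC = %.1f\n",
              x$n, x$n_subjects, x$rmse, x$aic))
  invisible(x)
}

#' Predict from a DoG fit
#'
#' @param object A `dog_fit`.
#' @param newdata Optional data frame with the fitted predictor column and
#'   `subject`; defaults to the training frame.
#' @param ... Unused.
#' @return Predicted errors in degrees. Subject-specific amplitudes are used
#'   where the subject was seen in training; the fixed effect otherwise.
#' @export
predict.dog_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  pred_col <- if (!is.na(object$predictor)) object$predictor else "x"
  if (!pred_col %in% names(newdata)) newdata <- serial_predictors(newdata)
  x <- newdata[[pred_col]]
  subj <- as.character(newdata$subject)
  a <- rep(object$alpha0, length(x))
  if (!is.null(object$alpha_subject)) {
    hit <- subj %in% names(object$alpha_subject)
    a[hit] <- object$alpha_subject[subj[hit]]
  }
  a * .dog_basis(x, object$w)
}

# ---- conditional (two-condition) DoG ---------------------------------------

# Sufficient statistics are separable because the two condition-specific
# bases have disjoint support, so each subject's covariance factorizes into
# a condition-0 and a condition-1 block sharing sigma_e.
.cond_neg2ll <- function(lam0, lam1, st0, st1) {
  den0 <- 1 + lam0 * st0$s; den1 <- 1 + lam1 * st1$s
  sw0 <- sum(st0$s / den0); sw1 <- sum(st1$s / den1)
  if (sw0 <= 0 || sw1 <= 0) return(list(val = Inf))
  a0 <- sum(st0$t / den0) / sw0
  k0 <- sum(st1$t / den1) / sw1
  Q0 <- sum(st0$q - 2 * a0 * st0$t + a0^2 * st0$s -
              lam0 * (st0$t - a0 * st0$s)^2 / den0)
  Q1 <- sum(st1$q - 2 * k0 * st1$t + k0^2 * st1$s -
              lam1 * (st1$t - k0 * st1$s)^2 / den1)
  N <- st0$N + st1$N
  Q <- Q0 + Q1
  if (Q <= 0) return(list(val = Inf))
  list(val = N * log(2 * pi * Q / N) + N + sum(log(den0)) + sum(log(den1)),
       a0 = a0, k0 = k0, Q = Q, N = N, den0 = den0, den1 = den1)
}

.cond_profile_lambdas <- function(st0, st1) {
  lam0 <- 0; lam1 <- 0
  for (it in 1:3) {
    f0 <- function(l) .cond_neg2ll(l, lam1, st0, st1)$val
    o0 <- stats::optimize(f0, c(0, 1e3), tol = 1e-7)
    lam0 <- if (f0(0) <= o0$objective) 0 else o0$minimum
    f1 <- function(l) .cond_neg2ll(lam0, l, st0, st1)$val
    o1 <- stats::optimize(f1, c(0, 1e3), tol = 1e-7)
    lam1 <- if (f1(0) <= o1$objective) 0 else o1$minimum
  }
  list(lam0 = lam0, lam1 = lam1,
       neg2ll = .cond_neg2ll(lam0, lam1, st0, st1)$val)
}

#' Fit the conditional (two-condition) multilevel DoG model
#'
#' Extends [fit_multilevel_dog()] to designs with two trial conditions
#' (e.g. whether the preceding trial required a response): independent
#' amplitudes `alpha0` (condition 0) and `k0` (condition 1), each with its
#' own subject-level random deviation, plus a width `w` for condition 0 and
#' a width offset `z_w` for condition 1. The amplitude difference is tested
#' with `z = (alpha0 - k0) / sqrt(se_alpha^2 + se_k^2)` against the standard
#' normal.
#'
#' @param data Trial table.
#' @param predictor `"delta_S"` or `"delta_R"`.
#' @param condition Name of a two-level column in `data` (or a vector); the
#'   *first* sorted level is condition 0 (amplitude `alpha0`).
#' @param fix_w,fix_z Optional fixed width / width offset.
#' @return Object of class `cond_dog_fit` with both amplitudes, their SEs,
#'   the difference z-test, widths and fit summaries.
#' @export
fit_conditional_dog <- function(data, predictor = c("delta_S", "delta_R"),
                                condition = "prev_condition",
                                fix_w = NULL, fix_z = NULL) {
  predictor <- match.arg(predictor)
  if (!predictor %in% names(data)) data <- serial_predictors(data)
  cond <- if (is.character(condition) && length(condition) == 1)
    data[[condition]] else condition
  y <- .circ_error(data)
  x <- data[[predictor]]
  keep <- !is.na(x) & !is.na(y) & !is.na(cond)
  y <- y[keep]; x <- x[keep]
  subj <- as.character(data$subject)[keep]
  cond <- factor(cond[keep])
  if (nlevels(cond) != 2) stop("condition must have exactly two levels")
  c1 <- cond == levels(cond)[2]
  if (min(table(cond)) < 50)
    warning("a condition has fewer than 50 trials; estimates may be unstable")
  single <- length(unique(subj)) < 2

  obj <- function(par) {
    w <- par[1]; z <- par[2]
    if (w <= 0.003 || w >= 0.997 || w + z <= 0.003 || w + z >= 0.997)
      return(1e12)
    g0 <- .dog_basis(x, w) * !c1
    g1 <- .dog_basis(x, w + z) * c1
    if (single) {
      a <- sum(g0 * y) / sum(g0 * g0); k <- sum(g1 * y) / sum(g1 * g1)
      sum((y - a * g0 - k * g1)^2)
    } else {
      st0 <- .ml_suff(y[!c1], .dog_basis(x[!c1], w), subj[!c1])
      st1 <- .ml_suff(y[c1], .dog_basis(x[c1], w + z), subj[c1])
      .cond_profile_lambdas(st0, st1)$neg2ll
    }
  }
  w0 <- if (is.null(fix_w)) 0.05 else fix_w
  z0 <- if (is.null(fix_z)) 0 else fix_z
  if (is.null(fix_w) || is.null(fix_z)) {
    if (is.null(fix_w) && is.null(fix_z)) {
      opt <- stats::optim(c(w0, z0), obj, method = "Nelder-Mead",
                          control = list(maxit = 300, reltol = 1e-8))
      w <- opt$par[1]; zw <- opt$par[2]
    } else if (is.null(fix_w)) {
      o <- stats::optimize(function(w) obj(c(w, z0)), c(0.005, 0.6))
      w <- o$minimum; zw <- z0
    } else {
      o <- stats::optimize(function(z) obj(c(w0, z)), c(-w0 + 0.005, 0.6))
      w <- w0; zw <- o$minimum
    }
  } else { w <- w0; zw <- z0 }

  g0 <- .dog_basis(x, w) * !c1
  g1 <- .dog_basis(x, w + zw) * c1
  if (single) {
    a0 <- sum(g0 * y) / sum(g0 * g0); k0 <- sum(g1 * y) / sum(g1 * g1)
    resid <- y - a0 * g0 - k0 * g1
    sig <- sqrt(sum(resid^2) / max(1, length(y) - 4))
    se_a <- sig / sqrt(sum(g0 * g0)); se_k <- sig / sqrt(sum(g1 * g1))
    loglik <- sum(stats::dnorm(y, a0 * g0 + k0 * g1,
                               sqrt(mean(resid^2)), log = TRUE))
  } else {
    st0 <- .ml_suff(y[!c1], .dog_basis(x[!c1], w), subj[!c1])
    st1 <- .ml_suff(y[c1], .dog_basis(x[c1], w + zw), subj[c1])
    pl <- .cond_profile_lambdas(st0, st1)
    res <- .cond_neg2ll(pl$lam0, pl$lam1, st0, st1)
    a0 <- res$a0; k0 <- res$k0
    sigma_e <- sqrt(res$Q / res$N)
    se_a <- sigma_e / sqrt(sum(st0$s / res$den0))
    se_k <- sigma_e / sqrt(sum(st1$s / res$den1))
    u0 <- pl$lam0 * (st0$t - a0 * st0$s) / res$den0
    u1 <- pl$lam1 * (st1$t - k0 * st1$s) / res$den1
    fit_vec <- numeric(length(y))
    fit_vec[!c1] <- (a0 + u0[match(subj[!c1], st0$subjects)]) *
      .dog_basis(x[!c1], w)
    fit_vec[c1] <- (k0 + u1[match(subj[c1], st1$subjects)]) *
      .dog_basis(x[c1], w + zw)
    resid <- y - fit_vec
    loglik <- -pl$neg2ll / 2
  }
  zd <- (a0 - k0) / sqrt(se_a^2 + se_k^2)
  structure(list(
    predictor = predictor, alpha0 = a0, k0 = k0,
    se_alpha0 = se_a, se_k0 = se_k,
    w = w, z_w = zw, peak = dog_peak(w), peak1 = dog_peak(w + zw),
    z_diff = zd, p_diff = 2 * stats::pnorm(-abs(zd)),
    condition_levels = levels(cond),
    rmse = sqrt(mean(resid^2)), loglik = loglik,
    n = length(y), n_subjects = length(unique(subj))
  ), class = "cond_dog_fit")
}

#' @export
print.cond_dog_fit <- function(x, ...) {
  cat("Conditional DoG fit (", x$predictor, ")\n", sep = "")
  cat(sprintf("  alpha0 [%s] = %.3f (SE %.3f)\n",
              x$condition_levels[1], x$alpha0, x$se_alpha0))
  cat(sprintf("  k0     [%s] = %.3f (SE %.3f)\n",
              x$condition_levels[2], x$k0, x$se_k0))
  cat(sprintf("  widths w = %.4f / %.4f; diff z = %.2f, p = %.3g\n",
              x$w, x$w + x$z_w, x$z_diff, x$p_diff))
  invisible(x)
}

# ---- controls ---------------------------------------------------------------

#' Permutation null distribution of the DoG amplitude
#'
#' Refits the DoG model after shuffling the temporal order of trials
#' (stimulus and response rows permuted jointly, within subject), which
#' destroys any true dependence between consecutive trials while preserving
#' each subject's marginal stimulus-response relation. Any amplitude
#' surviving the shuffle is spurious, caused by stimulus-dependent response
#' biases; comparing the observed amplitude against this null separates true
#' serial dependence from such confounds.
#'
#' @param data Trial table.
#' @param predictor `"delta_S"` or `"delta_R"`.
#' @param n Number of shuffles.
#' @param seed Random seed.
#' @param multilevel Use the multilevel fitter (default) or, with one
#'   subject, the single-level fitter.
#' @param fix_w Optional fixed width passed to the fitter (speeds up large
#'   permutation runs).
#' @return List with `observed` (alpha0), `null` (vector of shuffled
#'   alpha0), two-sided `p` (rank-based, add-one corrected), and the mean
#'   and sd of the null.
#' @export
shuffle_null_amplitude <- function(data, predictor = c("delta_S", "delta_R"),
                                   n = 1000, seed = NULL, fix_w = NULL,
                                   multilevel = NULL) {
  predictor <- match.arg(predictor)
  if (!is.null(seed)) set.seed(seed)
  data <- data[order(data$subject, data$trial), , drop = FALSE]
  if (is.null(multilevel)) multilevel <- length(unique(data$subject)) > 1
  fit1 <- function(d) {
    # predictors must be recomputed from the (possibly shuffled) trial order
    d <- d[setdiff(names(d), c("delta_S", "delta_R", "prev_condition"))]
    if (multilevel) fit_multilevel_dog(d, predictor, fix_w = fix_w)$alpha0
    else { fr <- .fit_frame(d, predictor); fit_dog(fr$x, fr$y, fix_w = fix_w)$alpha0 }
  }
  obs <- fit1(data)
  idx <- split(seq_len(nrow(data)), data$subject)
  null <- vapply(seq_len(n), function(b) {
    ord <- unlist(lapply(idx, sample), use.names = FALSE)
    d <- data[ord, , drop = FALSE]
    d$trial <- stats::ave(seq_len(nrow(d)), d$subject, FUN = seq_along)
    fit1(d)
  }, numeric(1))
  p <- (1 + sum(abs(null) >= abs(obs))) / (n + 1)
  list(observed = obs, null = null, p = p,
       null_mean = mean(null), null_sd = stats::sd(null))
}

#' Future-trial control fit
#'
#' Fits the DoG with the predictor computed from the *next* trial instead of
#' the previous one. True serial dependence is causal and cannot produce a
#' future effect, so a significant "future" amplitude flags stimulus-locked
#' response biases leaking into the predictor.
#'
#' @inheritParams shuffle_null_amplitude
#' @return A `dog_fit` on the future predictor.
#' @export
future_trial_control <- function(data, predictor = c("delta_S", "delta_R")) {
  predictor <- match.arg(predictor)
  data <- serial_predictors(data, future = TRUE)
  if (length(unique(data$subject)) > 1) fit_multilevel_dog(data, predictor)
  else { fr <- .fit_frame(data, predictor); fit_dog(fr$x, fr$y) }
}

#' Running-average error curve with jackknife errors
#'
#' Sliding-window mean of errors along the predictor axis (window centers
#' step by `window - overlap` degrees), averaged across subjects, with
#' leave-one-subject-out jackknife standard errors.
#'
#' @param data Trial table.
#' @param predictor `"delta_S"` or `"delta_R"`.
#' @param window Window width in degrees.
#' @param overlap Overlap between consecutive windows in degrees.
#' @return Data frame with `center`, `mean`, `se`, `n_trials`.
#' @export
running_average_curve <- function(data, predictor = c("delta_S", "delta_R"),
                                  window = 15, overlap = 14) {
  predictor <- match.arg(predictor)
  fr <- .fit_frame(data, predictor)
  step <- window - overlap
  centers <- seq(min(fr$x) + window / 2, max(fr$x) - window / 2, by = step)
  subjects <- unique(fr$subject)
  per_subj <- vapply(subjects, function(s) {
    xs <- fr$x[fr$subject == s]; ys <- fr$y[fr$subject == s]
    vapply(centers, function(ct) {
      inw <- abs(xs - ct) <= window / 2
      if (any(inw)) mean(ys[inw]) else NA_real_
    }, numeric(1))
  }, numeric(length(centers)))
  per_subj <- matrix(per_subj, nrow = length(centers))
  m <- rowMeans(per_subj, na.rm = TRUE)
  nsub <- length(subjects)
  se <- vapply(seq_along(centers), function(i) {
    v <- per_subj[i, ]
    v <- v[!is.na(v)]
    k <- length(v)
    if (k < 2) return(NA_real_)
    loo <- (sum(v) - v) / (k - 1)
    sqrt((k - 1) / k * sum((loo - mean(loo))^2))
  }, numeric(1))
  ntr <- vapply(centers, function(ct) sum(abs(fr$x - ct) <= window / 2),
                numeric(1))
  data.frame(center = centers, mean = m, se = se, n_trials = ntr)
}
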