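# Deciding between predictor models of serial dependence (previous stimulus
# delta_S vs previous response delta_R, and competitor-size variants):
# rmse permutation test, subject-stratified cross-validation, dominance
# analysis, AIC / likelihood-ratio reporting.

.fit_engine <- function(data, predictor, engine) {
  if (engine == "dog") {
    if (length(unique(data$subject)) > 1) fit_multilevel_dog(data, predictor)
    else { fr <- .fit_frame(data, predictor); fit_dog(fr$x, fr$y) }
  } else {
    fit_linear_mixed(data, predictors = predictor)
  }
}

.engine_rmse <- function(fit, data, predictor, engine) {
  if (engine == "dog") {
    if (!predictor %in% names(data)) data <- serial_predictors(data)
    y <- .circ_error(data)
    keep <- !is.na(y) & !is.na(data[[predictor]])
    pred <- predict(fit, data[keep, , drop = FALSE])
    sqrt(mean((y[keep] - pred)^2))
  } else {
    y <- data$response - data$stimulus
    keep <- !is.na(y) & !is.na(data[[predictor]])
    pred <- predict(fit, data[keep, , drop = FALSE])
    sqrt(mean((y[keep] - pred)^2))
  }
}

#' Permutation test of the rmse difference between predictor models
#'
#' Fits the serial-dependence model once with each predictor and computes
#' the observed `rmse(delta_S) - rmse(delta_R)`. The null distribution comes
#' from refits in which each predictor column is independently permuted
#' across trials (within subject), removing any true temporal dependence
#' while keeping the marginal predictor and error distributions. The
#' two-sided p is the add-one-corrected exceedance proportion.
#'
#' @param data Trial table.
#' @param n Number of permutation replicas.
#' @param seed Random seed.
#' @param engine `"dog"` (multilevel DoG) or `"linear"` (linear mixed model,
#'   for size tasks).
#' @return List of class `comparison_test`: `rmse_S`, `rmse_R`,
#'   `rmse_diff`, `null` draws, `p`.
#' @export
rmse_permutation_test <- function(data, n = 1000, seed = NULL,
                                  engine = c("dog", "linear")) {
  engine <- match.arg(engine)
  if (!is.null(seed)) set.seed(seed)
  if (!all(c("delta_S", "delta_R") %in% names(data)))
    data <- serial_predictors(data)
  fS <- .fit_engine(data, "delta_S", engine)
  fR <- .fit_engine(data, "delta_R", engine)
  rmse_S <- .engine_rmse(fS, data, "delta_S", engine)
  rmse_R <- .engine_rmse(fR, data, "delta_R", engine)
  obs <- rmse_S - rmse_R
  idx <- split(seq_len(nrow(data)), data$subject)
  null <- vapply(seq_len(n), function(b) {
    d <- data
    for (ii in idx) {
      d$delta_S[ii] <- d$delta_S[ii][sample(length(ii))]
      d$delta_R[ii] <- d$delta_R[ii][sample(length(ii))]
    }
    f1 <- .fit_engine(d, "delta_S", engine)
    f2 <- .fit_engine(d, "delta_R", engine)
    .engine_rmse(f1, d, "delta_S", engine) -
      .engine_rmse(f2, d, "delta_R", engine)
  }, numeric(1))
  p <- (1 + sum(abs(null) >= abs(obs))) / (n + 1)
  structure(list(rmse_S = rmse_S, rmse_R = rmse_R, rmse_diff = obs,
                 null = null, p = p, n = n, engine = engine),
            class = "comparison_test")
}

#' @export
print.comparison_test <- function(x, ...) {
  cat(sprintf("rmse(delta_S) = %.4f, rmse(delta_R) = %.4f, diff = %.4f\n",
              x$rmse_S, x$rmse_R, x$rmse_diff))
  cat(sprintf("permutation p = %.4g (%d replicas, %s engine)\n",
              x$p, x$n, x$engine))
  invisible(x)
}

#' Subject-stratified cross-validation of predictor models
#'
#' At each iteration the data are split into train and test sets at
#' `train_frac`, stratified so every subject contributes proportionally to
#' both; both predictor models are fitted on the training set and scored by
#' test-set rmse. The headline number is the fraction of iterations in
#' which the delta_R model predicts unseen data better.
#'
#' @param data Trial table.
#' @param n Number of iterations.
#' @param train_frac Fraction of each subject's trials in the training set.
#' @param seed Random seed.
#' @param engine `"dog"` or `"linear"`.
#' @return List of class `cv_result`: `win_fraction_R` (proportion of
#'   iterations with `rmse_R < rmse_S` on test data), `rmse_diff`
#'   (per-iteration `rmse_S - rmse_R`).
#' @export
cross_validate <- function(data, n = 1000, train_frac = 0.7, seed = NULL,
                           engine = c("dog", "linear")) {
  engine <- match.arg(engine)
  if (!is.null(seed)) set.seed(seed)
  if (!all(c("delta_S", "delta_R") %in% names(data)))
    data <- serial_predictors(data)
  idx <- split(seq_len(nrow(data)), data$subject)
  if (length(idx) < 2) stop("cross-validation needs at least 2 subjects")
  diffs <- vapply(seq_len(n), function(b) {
    tr <- unlist(lapply(idx, function(ii)
      sample(ii, max(2, round(train_frac * length(ii))))), use.names = FALSE)
    train <- data[sort(tr), , drop = FALSE]
    test <- data[-sort(tr), , drop = FALSE]
    fS <- .fit_engine(train, "delta_S", engine)
    fR <- .fit_engine(train, "delta_R", engine)
    .engine_rmse(fS, test, "delta_S", engine) -
      .engine_rmse(fR, test, "delta_R", engine)
  }, numeric(1))
  structure(list(win_fraction_R = mean(diffs > 0), rmse_diff = diffs,
                 n = n, train_frac = train_frac, engine = engine),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "cross-validation (%d iterations, %.0f%% train): delta_R wins %.1f%%\n",
    x$n, 100 * x$train_frac, 100 * x$win_fraction_R))
  invisible(x)
}

# marginal R^2 of a fixed-effects prediction
.marginal_r2 <- function(y, pred) 1 - sum((y - pred)^2) / sum((y - mean(y))^2)

#' Dominance analysis of two history predictors
#'
#' Compares the relative importance of two predictors of trial-wise errors
#' (by default `delta_S` and `delta_R`) with classic two-predictor dominance
#' analysis on a linear mixed model (random subject intercept): each
#' predictor's general dominance is the average of its sole-model R^2 and
#' its incremental R^2 over the other predictor (marginal, fixed-effects
#' R^2), normalized to shares. Trials are restricted to the `+/-
#' range_limit` band (where the DoG is near-linear) and each iteration uses
#' a subject-stratified subsample.
#'
#' @param data Trial table (errors circular; use `predictors` columns
#'   already present or computable via [serial_predictors()]).
#' @param predictors Character vector of two predictor column names.
#' @param range_limit Keep trials with both `|predictors| <= range_limit`.
#' @param n Number of subsampling iterations.
#' @param subsample Fraction of each subject's trials per iteration.
#' @param seed Random seed.
#' @param circular_error Use wrapped orientation errors (else linear).
#' @return List of class `dominance_result`: per-iteration shares of each
#'   predictor and their difference (`share2 - share1`), plus skipped
#'   iteration count.
#' @export
dominance_analysis <- function(data, predictors = c("delta_S", "delta_R"),
                               range_limit = 40, n = 1000, subsample = 0.75,
                               seed = NULL, circular_error = TRUE) {
  stopifnot(length(predictors) == 2)
  if (!is.null(seed)) set.seed(seed)
  if (!all(predictors %in% names(data))) data <- serial_predictors(data)
  y <- if (circular_error) .circ_error(data) else data$response - data$stimulus
  x1 <- data[[predictors[1]]]; x2 <- data[[predictors[2]]]
  keep <- !is.na(y) & !is.na(x1) & !is.na(x2) &
    abs(x1) <= range_limit & abs(x2) <= range_limit
  df <- data.frame(y = y[keep], x1 = x1[keep], x2 = x2[keep],
                   subject = factor(data$subject[keep]))
  idx <- split(seq_len(nrow(df)), df$subject)
  skipped <- 0L
  shares <- matrix(NA_real_, n, 2)
  for (b in seq_len(n)) {
    ii <- sort(unlist(lapply(idx, function(v)
      sample(v, max(2, round(subsample * length(v))))), use.names = FALSE))
    d <- df[ii, , drop = FALSE]
    r2 <- tryCatch({
      f1 <- lme4::lmer(y ~ x1 + (1 | subject), data = d, REML = FALSE)
      f2 <- lme4::lmer(y ~ x2 + (1 | subject), data = d, REML = FALSE)
      f12 <- lme4::lmer(y ~ x1 + x2 + (1 | subject), data = d, REML = FALSE)
      pred <- function(f, nd) {
        X <- stats::model.matrix(stats::terms(f), nd)
        drop(X %*% lme4::fixef(f))
      }
      c(.marginal_r2(d$y, pred(f1, d)), .marginal_r2(d$y, pred(f2, d)),
        .marginal_r2(d$y, pred(f12, d)))
    }, error = function(e) NULL)
    if (is.null(r2) || r2[3] <= 0) { skipped <- skipped + 1L; next }
    g1 <- (r2[1] + (r2[3] - r2[2])) / 2
    g2 <- (r2[2] + (r2[3] - r2[1])) / 2
    shares[b, ] <- c(g1, g2) / (g1 + g2)
  }
  structure(list(predictors = predictors, share1 = shares[, 1],
                 share2 = shares[, 2],
                 share_diff = shares[, 2] - shares[, 1],
                 skipped = skipped, n = n),
            class = "dominance_result")
}

#' @export
print.dominance_result <- function(x, ...) {
  cat(sprintf("dominance: %s %.1f%% vs %s %.1f%% (mean shares, %d iterations, %d skipped)\n",
              x$predictors[1], 100 * mean(x$share1, na.rm = TRUE),
              x$predictors[2], 100 * mean(x$share2, na.rm = TRUE),
              x$n, x$skipped))
  invisible(x)
}

#' AIC and likelihood-ratio comparison of two fitted models
#'
#' For two fits on identical rows (same n), reports both AICs, the
#' likelihood-ratio statistic `2 * (loglik_2 - loglik_1)`, and — because
#' the usual chi-squared reference degenerates for non-nested models with
#' equal parameter counts — a Vuong-style standardized statistic based on
#' the pointwise log-likelihood differences, with a two-sided normal p
#' (positive z favors the second model).
#'
#' @param fit1,fit2 Fits carrying `loglik`, `aic`, `n`, `n_par` and
#'   `pointwise_ll` (a [fit_multilevel_dog()], [fit_dog()] or
#'   [fit_linear_mixed()] result).
#' @return List of class `aic_comparison`.
#' @export
aic_lrt_compare <- function(fit1, fit2) {
  if (fit1$n != fit2$n)
    stop("fits use different numbers of rows (", fit1$n, " vs ", fit2$n,
         "); compare models on identical data")
  lrt <- 2 * (fit2$loglik - fit1$loglik)
  d <- fit2$pointwise_ll - fit1$pointwise_ll
  vz <- if (stats::sd(d) > 0) sum(d) / (stats::sd(d) * sqrt(length(d)))
        else 0
  structure(list(aic1 = fit1$aic, aic2 = fit2$aic,
                 aic_diff = fit2$aic - fit1$aic,
                 lrt = lrt, vuong_z = vz,
                 p = 2 * stats::pnorm(-abs(vz)), n = fit1$n),
            class = "aic_comparison")
}

#' @export
print.aic_comparison <- function(x, ...) {
  cat(sprintf("AIC: %.1f vs %.1f (diff %.1f); LRT = %.2f; Vuong z = %.2f, p = %.3g\n",
              x$aic1, x$aic2, x$aic_diff, x$lrt, x$vuong_z, x$p))
  invisible(x)
}
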