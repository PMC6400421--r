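# Signal-detection and linear mixed-effects analyses for the forced-choice
# dual task and the size-estimation experiments.

#' Add linear (size-task) history predictors
#'
#' Like [serial_predictors()] but for size-estimation tables, where
#' differences are plain (not circular): `delta_S`/`delta_R` are the
#' previous stimulus/response minus the current stimulus, and competitor
#' sizes (if present) yield `delta_C1`, `delta_C2`, ... ordered as stored.
#'
#' @param data Size-task trial table.
#' @return `data` with predictor columns added.
#' @export
size_predictors <- function(data) {
  data <- data[order(data$subject, data$trial), , drop = FALSE]
  n <- nrow(data)
  subj <- as.character(data$subject)
  first <- c(TRUE, subj[-1] != subj[-n])
  prev_stim <- c(NA, data$stimulus[-n]); prev_stim[first] <- NA
  prev_resp <- c(NA, data$response[-n]); prev_resp[first] <- NA
  data$delta_S <- prev_stim - data$stimulus
  data$delta_R <- prev_resp - data$stimulus
  if ("competitor_sizes_json" %in% names(data)) {
    comp <- lapply(data$competitor_sizes_json, jsonlite::fromJSON)
    k <- max(lengths(comp))
    for (j in seq_len(k)) {
      data[[paste0("delta_C", j)]] <- vapply(comp, function(v)
        if (length(v) >= j) v[j] else NA_real_, numeric(1)) - data$stimulus
    }
  }
  data
}

#' Signal-detection analysis of Yes/No vertical judgments
#'
#' Converts trial-wise forced-choice data into hit and false-alarm rates per
#' subject x congruency x SNR x |deviation| cell (hit: "vertical" response
#' when the tilt deviation is toward vertical, i.e. positive; false alarm:
#' "vertical" response to a horizontal-ward tilt) and computes d-prime and
#' criterion with the 1/(2N) correction for extreme rates.
#'
#' @param data Data frame with columns `subject`, `congruency`, `snr`,
#'   `deviation` (signed degrees, positive toward vertical) and
#'   `response_vertical` (logical/0-1).
#' @return Data frame of class `sdt_result` with per-cell `hit_rate`,
#'   `fa_rate`, `dprime`, `criterion`, `n_signal`, `n_noise`.
#' @export
compute_sdt <- function(data) {
  stopifnot(all(c("subject", "congruency", "snr", "deviation",
                  "response_vertical") %in% names(data)))
  data$absdev <- abs(data$deviation)
  key <- interaction(data$subject, data$congruency, data$snr, data$absdev,
                     drop = TRUE)
  cells <- lapply(split(data, key), function(d) {
    sig <- d$deviation > 0
    ns <- sum(sig); nn <- sum(!sig)
    if (ns == 0 || nn == 0) return(NULL)  # empty half-cell: excluded
    h <- sum(d$response_vertical[sig]) / ns
    f <- sum(d$response_vertical[!sig]) / nn
    h <- min(max(h, 1 / (2 * ns)), 1 - 1 / (2 * ns))
    f <- min(max(f, 1 / (2 * nn)), 1 - 1 / (2 * nn))
    data.frame(subject = d$subject[1], congruency = d$congruency[1],
               snr = d$snr[1], deviation = d$absdev[1],
               hit_rate = h, fa_rate = f,
               dprime = stats::qnorm(h) - stats::qnorm(f),
               criterion = -(stats::qnorm(h) + stats::qnorm(f)) / 2,
               n_signal = ns, n_noise = nn)
  })
  out <- do.call(rbind, cells[!vapply(cells, is.null, logical(1))])
  rownames(out) <- NULL
  class(out) <- c("sdt_result", "data.frame")
  out
}

#' Linear mixed model for d-prime
#'
#' Fits `dprime ~ deviation * snr` with a random subject intercept, for one
#' congruency condition: slopes for the absolute deviation from the
#' diagonal, for SNR, and their interaction.
#'
#' @param sdt A [compute_sdt()] result.
#' @param congruency Which condition to fit (level of the `congruency`
#'   column).
#' @return A `lmm_fit` (see [fit_linear_mixed()]).
#' @export
fit_dprime_model <- function(sdt, congruency) {
  d <- sdt[sdt$congruency == congruency, , drop = FALSE]
  fit_linear_mixed(d, response = "dprime",
                   predictors = c("deviation", "snr", "deviation:snr"))
}

#' Baseline-corrected sensitivity change per SNR
#'
#' Estimates, per subject, the change in d-prime attributable to the
#' preceding task: the Congruent condition's mean d-prime at each SNR
#' (collapsed over deviations) minus that subject's Incongruent grand mean
#' (the baseline, collapsed over SNR and deviation). A paired t-test
#' compares the two extreme SNR levels across subjects.
#'
#' @param sdt A [compute_sdt()] result with both congruency conditions.
#' @param congruent,incongruent Level names.
#' @return List with `delta_dprime` (SNR x subject matrix), `means` per
#'   SNR, and `extremes_test` (paired t-test lowest vs highest SNR).
#' @export
baseline_delta_dprime <- function(sdt, congruent = "congruent",
                                  incongruent = "incongruent") {
  stopifnot(all(c(congruent, incongruent) %in% sdt$congruency))
  base <- tapply(sdt$dprime[sdt$congruency == incongruent],
                 sdt$subject[sdt$congruency == incongruent], mean)
  cg <- sdt[sdt$congruency == congruent, , drop = FALSE]
  m <- tapply(cg$dprime, list(snr = cg$snr, subject = cg$subject), mean)
  dd <- sweep(m, 2, base[colnames(m)])
  snrs <- as.numeric(rownames(dd))
  lo <- which.min(snrs); hi <- which.max(snrs)
  tt <- stats::t.test(dd[hi, ], dd[lo, ], paired = TRUE)
  list(delta_dprime = dd, means = rowMeans(dd, na.rm = TRUE),
       extremes_test = tt)
}

#' Difference curve of "vertical" response proportions
#'
#' Computes, per signed deviation and SNR level, the difference in the
#' proportion of "vertical" responses between the Incongruent and Congruent
#' conditions (incongruent minus congruent, averaged over subjects), and
#' fits the two SNR levels' curves jointly with the conditional DoG model
#' (subject-level proportions as the response, signed deviation as the
#' predictor).
#'
#' @param data Trial-level data as in [compute_sdt()].
#' @param snr_levels The two SNR levels to contrast (default the extremes).
#' @param congruent,incongruent Level names.
#' @return List with `curve` (deviation x snr difference proportions) and
#'   `fit` (a `cond_dog_fit`; `alpha0` is the amplitude for the first SNR
#'   level, `k0` for the second).
#' @export
delta_p_vertical <- function(data, snr_levels = NULL,
                             congruent = "congruent",
                             incongruent = "incongruent") {
  if (is.null(snr_levels)) snr_levels <- range(unique(data$snr))
  agg <- function(cond, snr) {
    d <- data[data$congruency == cond & data$snr == snr, , drop = FALSE]
    tapply(d$response_vertical, list(d$deviation, d$subject), mean)
  }
  rows <- list()
  for (s in snr_levels) {
    pc <- agg(congruent, s); pi <- agg(incongruent, s)
    common <- intersect(rownames(pc), rownames(pi))
    subj <- intersect(colnames(pc), colnames(pi))
    diffm <- pi[common, subj, drop = FALSE] - pc[common, subj, drop = FALSE]
    rows[[as.character(s)]] <- data.frame(
      snr = s,
      deviation = rep(as.numeric(common), times = length(subj)),
      subject = rep(subj, each = length(common)),
      dp = as.vector(diffm))
  }
  long <- do.call(rbind, rows)
  long <- long[!is.na(long$dp), , drop = FALSE]
  curve <- stats::aggregate(dp ~ deviation + snr, long, mean)
  cfit <- .delta_p_cond_fit(long, snr_levels)
  list(curve = curve, fit = cfit)
}

# conditional DoG fit on difference-proportion data (y is already an
# "error"-like quantity; reuse the conditional machinery directly)
.delta_p_cond_fit <- function(long, snr_levels) {
  y <- long$dp; x <- long$deviation
  subj <- as.character(long$subject)
  cond <- factor(long$snr, levels = snr_levels)
  c1 <- cond == levels(cond)[2]
  obj <- function(par) {
    w <- par[1]; z <- par[2]
    if (w <= 0.003 || w >= 0.9 || w + z <= 0.003 || w + z >= 0.9) return(1e12)
    st0 <- .ml_suff(y[!c1], .dog_basis(x[!c1], w), subj[!c1])
    st1 <- .ml_suff(y[c1], .dog_basis(x[c1], w + z), subj[c1])
    .cond_profile_lambdas(st0, st1)$neg2ll
  }
  opt <- stats::optim(c(0.05, 0), obj, method = "Nelder-Mead",
                      control = list(maxit = 200))
  w <- opt$par[1]; zw <- opt$par[2]
  st0 <- .ml_suff(y[!c1], .dog_basis(x[!c1], w), subj[!c1])
  st1 <- .ml_suff(y[c1], .dog_basis(x[c1], w + zw), subj[c1])
  pl <- .cond_profile_lambdas(st0, st1)
  res <- .cond_neg2ll(pl$lam0, pl$lam1, st0, st1)
  sigma_e <- sqrt(res$Q / res$N)
  se_a <- sigma_e / sqrt(sum(st0$s / res$den0))
  se_k <- sigma_e / sqrt(sum(st1$s / res$den1))
  zd <- (res$a0 - res$k0) / sqrt(se_a^2 + se_k^2)
  structure(list(predictor = "deviation", alpha0 = res$a0, k0 = res$k0,
                 se_alpha0 = se_a, se_k0 = se_k, w = w, z_w = zw,
                 peak = dog_peak(w), peak1 = dog_peak(w + zw),
                 z_diff = zd, p_diff = 2 * stats::pnorm(-abs(zd)),
                 condition_levels = as.character(snr_levels),
                 rmse = sqrt(res$Q / res$N), loglik = -pl$neg2ll / 2,
                 n = res$N, n_subjects = length(unique(subj))),
            class = "cond_dog_fit")
}

#' Linear mixed-effects model with a random subject intercept
#'
#' The workhorse for size-estimation errors and d-prime modeling: fixed
#' effects for the given predictors, a random intercept per subject,
#' maximum-likelihood estimation via lme4. Significance of the fixed
#' effects uses z-tests (estimate / SE, standard normal). Fitting the
#' highly collinear `delta_S` and `delta_R` together is refused — compare
#' them as separate models instead.
#'
#' @param data Data frame with `subject`, the response column and the
#'   predictor columns (error responses are `response - stimulus` when
#'   `response = "error"` and no `error` column exists).
#' @param response Response column name, or `"error"` for report minus
#'   truth.
#' @param predictors Character vector of fixed-effect terms (may include
#'   interactions like `"a:b"`).
#' @return Object of class `lmm_fit` with `coefficients` (estimate, se, z,
#'   p), `aic`, `loglik`, `n`, `n_par`, `pointwise_ll` and the `lme4` fit
#'   in `$model`.
#' @export
fit_linear_mixed <- function(data, response = "error",
                             predictors = c("delta_S")) {
  if (all(c("delta_S", "delta_R") %in% predictors))
    stop("delta_S and delta_R are collinear by construction; ",
         "fit them as separate models")
  if (response == "error" && !"error" %in% names(data))
    data$error <- data$response - data$stimulus
  keep <- stats::complete.cases(
    data[, c(response, "subject",
             unique(unlist(strsplit(predictors, ":", fixed = TRUE))))])
  d <- data[keep, , drop = FALSE]
  d$subject <- factor(d$subject)
  form <- stats::as.formula(paste(
    response, "~", paste(predictors, collapse = " + "), "+ (1 | subject)"))
  fit <- lme4::lmer(form, data = d, REML = FALSE)
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- est / se
  coefs <- data.frame(estimate = est, se = se, z = z,
                      p = 2 * stats::pnorm(-abs(z)))
  mu <- stats::fitted(fit)
  sig <- stats::sigma(fit)
  ll_i <- stats::dnorm(d[[response]], mu, sig, log = TRUE)
  ll <- as.numeric(stats::logLik(fit))
  structure(list(coefficients = coefs, aic = stats::AIC(fit), loglik = ll,
                 n = nrow(d), n_par = attr(stats::logLik(fit), "df"),
                 pointwise_ll = ll_i, model = fit,
                 response = response, predictors = predictors,
                 singular = lme4::isSingular(fit)),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Linear mixed model:", x$response, "~",
      paste(x$predictors, collapse = " + "), "+ (1 | subject)\n")
  print(round(x$coefficients, 4))
  cat(sprintf("n = %d, logLik = %.1f, AIC = %.1f%s\n", x$n, x$loglik, x$aic,
              if (isTRUE(x$singular)) " (singular fit)" else ""))
  invisible(x)
}

#' Predict from a linear mixed fit
#'
#' @param object A `lmm_fit`.
#' @param newdata Data frame with predictor columns and `subject`.
#' @param ... Unused.
#' @return Predictions including the subject random intercept where the
#'   subject was in training (population level otherwise).
#' @export
predict.lmm_fit <- function(object, newdata, ...) {
  newdata$subject <- factor(as.character(newdata$subject))
  stats::predict(object$model, newdata = newdata, allow.new.levels = TRUE)
}
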