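test_that("the DoG curve is odd with peak height alpha at 1/(w sqrt(2))", {
  expect_equal(dog(0, 3, 0.05), 0)
  expect_equal(dog(dog_peak(0.05), 3, 0.05), 3)
  x <- runif(20, -90, 90)
  expect_equal(dog(-x, 1.5, 0.07), -dog(x, 1.5, 0.07))
  # the peak really is the maximum
  xs <- seq(0, 90, 0.01)
  expect_equal(xs[which.max(dog(xs, 1, 0.05))], dog_peak(0.05),
               tolerance = 0.01)
})

test_that("profile fit equals an lme4 random-slope fit at the same width", {
  tab <- make_adjustment_data(n_subjects = 5, n_trials = 200, alpha = 2,
                              w = 0.05, sigma = 8, alpha_sd = 1, seed = 81)
  f <- fit_multilevel_dog(tab, "delta_S", fix_w = 0.05)
  pr <- serial_predictors(tab)
  err <- wrap_delta(pr$response, pr$stimulus)
  g <- dog(pr$delta_S, 1, 0.05)
  keep <- !is.na(g)
  d <- data.frame(y = err[keep], g = g[keep], subject = pr$subject[keep])
  lf <- lme4::lmer(y ~ 0 + g + (0 + g | subject), data = d, REML = FALSE)
  expect_equal(f$alpha0, unname(lme4::fixef(lf)), tolerance = 1e-6)
  expect_equal(f$loglik, as.numeric(logLik(lf)), tolerance = 1e-6)
  expect_equal(f$se_alpha0, unname(sqrt(diag(as.matrix(vcov(lf))))),
               tolerance = 1e-6)
})

test_that("amplitude estimate is exactly equivariant under error negation", {
  tab <- make_adjustment_data(n_subjects = 4, n_trials = 200, alpha = 1.5,
                              seed = 82)
  f1 <- fit_multilevel_dog(tab, "delta_S", fix_w = 0.06)
  neg <- tab
  err <- wrap_delta(tab$response, tab$stimulus)
  neg$response <- wrap_orientation(tab$stimulus - err)
  f2 <- fit_multilevel_dog(neg, "delta_S", fix_w = 0.06)
  expect_equal(f2$alpha0, -f1$alpha0, tolerance = 1e-9)
})

test_that("fitted width lands in the empirical band when generating at w = 0.04", {
  tab <- make_adjustment_data(n_subjects = 12, n_trials = 500, alpha = 2,
                              w = 0.04, sigma = 8, seed = 83)
  f <- fit_multilevel_dog(tab, "delta_S")
  expect_gt(f$w, 0.039 - 0.018)
  expect_lt(f$w, 0.039 + 0.018)
})

test_that("conditional fit recovers opposite amplitudes and the Eq-5 z oracle", {
  # build a two-condition table directly from the generative model:
  # condition a gets +1.76, condition b gets -0.82
  set.seed(84)
  n <- 6000
  subj <- rep(sprintf("s%02d", 1:10), each = n / 10)
  x <- sample(seq(-60, 60, 15), n, replace = TRUE)
  cond <- sample(c("resp", "catch"), n, replace = TRUE)
  y <- ifelse(cond == "resp", dog(x, 1.76, 0.05), dog(x, -0.82, 0.03)) +
    rnorm(n, 0, 7)
  tab <- data.frame(subject = subj, trial = sequence(rep(n / 10, 10)),
                    stimulus = 90, response = wrap_orientation(90 + y),
                    delta_S = x)
  f <- fit_conditional_dog(tab, "delta_S", condition = cond)
  # levels sort: catch first -> alpha0 is the negative one
  expect_lt(f$alpha0, 0)
  expect_gt(f$k0, 0)
  expect_lt(abs(f$k0 - 1.76), 3 * f$se_k0)
  expect_lt(abs(f$alpha0 + 0.82), 3 * f$se_alpha0)
  expect_lt(f$p_diff, 0.001)
  expect_equal(f$z_diff,
               (f$alpha0 - f$k0) / sqrt(f$se_alpha0^2 + f$se_k0^2))
})

test_that("identical conditions give a centered z difference", {
  set.seed(85)
  zs <- replicate(12, {
    tab <- make_adjustment_data(n_subjects = 4, n_trials = 200, alpha = 1,
                                seed = sample.int(1e6, 1))
    tab <- serial_predictors(tab)
    cond <- sample(c("a", "b"), nrow(tab), replace = TRUE)
    fit_conditional_dog(tab, "delta_S", condition = cond)$z_diff
  })
  expect_lt(abs(mean(zs)), 1)
  expect_gt(mean(abs(zs) < 2.5), 0.8)
})

test_that("shuffle null: spurious delta_R dependence appears with an
           orientation bias and vanishes after residualization", {
  tab <- make_adjustment_data(n_subjects = 6, n_trials = 400, alpha = 0,
                              sigma = 4, seed = 86,
                              bias = orientation_bias_default(3))
  sn_raw <- shuffle_null_amplitude(tab, "delta_R", n = 60, seed = 87,
                                   fix_w = 0.05)
  # the shuffled fits keep finding a positive "serial dependence" that is
  # purely the stimulus-locked bias
  expect_gt(mean(sn_raw$null), 0.3)
  resid <- residualize_orientation_bias(tab)$data
  sn_res <- shuffle_null_amplitude(resid, "delta_R", n = 60, seed = 88,
                                   fix_w = 0.05)
  expect_lt(abs(mean(sn_res$null)), abs(mean(sn_raw$null)) / 3)
  # p-value equals its rank-based definition
  expect_equal(sn_res$p,
               (1 + sum(abs(sn_res$null) >= abs(sn_res$observed))) /
                 (length(sn_res$null) + 1))
})

test_that("future-trial control is null for a causal generator", {
  tab <- make_adjustment_data(n_subjects = 8, n_trials = 400, alpha = 2,
                              sigma = 8, seed = 89)
  f_past <- fit_multilevel_dog(tab, "delta_S", fix_w = 0.05)
  f_fut <- future_trial_control(tab, "delta_S")
  expect_lt(f_past$p, 0.01)
  expect_gt(f_fut$p, 0.01)
  # the last trial of each subject has no future predictor
  pr <- serial_predictors(tab, future = TRUE)
  last <- !duplicated(pr$subject, fromLast = TRUE)
  expect_true(all(is.na(pr$delta_S[last])))
})

test_that("running average curve: flat data, 1-degree steps, jackknife oracle", {
  tab <- data.frame(subject = rep(c("a", "b", "c"), each = 100),
                    trial = rep(1:100, 3), stimulus = 90,
                    response = wrap_orientation(90 + 2),
                    delta_S = rep(seq(-49.5, 49.5, 1), 3))
  rc <- running_average_curve(tab, "delta_S")
  expect_equal(diff(rc$center), rep(1, length(rc$center) - 1))
  expect_equal(rc$mean, rep(2, nrow(rc)), tolerance = 1e-9)
  expect_equal(rc$se, rep(0, nrow(rc)), tolerance = 1e-9)
  # jackknife closed form on three subjects with distinct errors
  tab$response <- wrap_orientation(90 + rep(c(1, 2, 6), each = 100))
  rc2 <- running_average_curve(tab, "delta_S")
  v <- c(1, 2, 6)
  loo <- (sum(v) - v) / 2
  se_hand <- sqrt(2 / 3 * sum((loo - mean(loo))^2))
  expect_equal(rc2$se[5], se_hand, tolerance = 1e-9)
})
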