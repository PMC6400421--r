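test_that("d-prime arithmetic: null, textbook case, extreme-rate correction", {
  d <- make_choice_data(n_subjects = 2, n_per_cell = 20, slope_base = 0,
                        seed = 1)
  sdt <- compute_sdt(d)
  expect_true(all(abs(sdt$dprime) < 3))          # finite despite extremes
  # hit = fa -> d' = 0: construct directly
  tab <- data.frame(subject = "s", congruency = "c", snr = 0,
                    deviation = rep(c(-5, 5), each = 10),
                    response_vertical = rep(c(TRUE, FALSE), 10))
  s0 <- compute_sdt(tab)
  expect_equal(s0$dprime, 0)
  # hit .8 / fa .2 -> 2 * qnorm(.8)
  tab2 <- data.frame(subject = "s", congruency = "c", snr = 0,
                     deviation = rep(c(5, -5), each = 10),
                     response_vertical = c(rep(TRUE, 8), rep(FALSE, 2),
                                           rep(TRUE, 2), rep(FALSE, 8)))
  s2 <- compute_sdt(tab2)
  expect_equal(s2$dprime, 2 * qnorm(0.8), tolerance = 1e-9)
  # 20 signal trials all hits -> corrected rate 0.975
  tab3 <- data.frame(subject = "s", congruency = "c", snr = 0,
                     deviation = rep(c(5, -5), each = 20),
                     response_vertical = c(rep(TRUE, 20), rep(FALSE, 15),
                                           rep(TRUE, 5)))
  expect_equal(compute_sdt(tab3)$hit_rate, 1 - 1 / 40)
})

test_that("d-prime is antisymmetric under swapping hits and false alarms", {
  tab <- data.frame(subject = "s", congruency = "c", snr = 0,
                    deviation = rep(c(5, -5), each = 20),
                    response_vertical = c(rep(TRUE, 15), rep(FALSE, 5),
                                          rep(TRUE, 8), rep(FALSE, 12)))
  swapped <- tab
  swapped$deviation <- -swapped$deviation
  expect_equal(compute_sdt(swapped)$dprime, -compute_sdt(tab)$dprime)
})

test_that("the d-prime model recovers a deviation slope near the generated one", {
  d <- make_choice_data(n_subjects = 14, n_per_cell = 40, slope_base = 0.05,
                        snr_effect = 0, seed = 2)
  sdt <- compute_sdt(d)
  f <- fit_dprime_model(sdt, "incongruent")
  est <- f$coefficients
  expect_lt(est["deviation", "p"], 0.001)
  expect_lt(abs(est["deviation", "estimate"] - 0.07), 0.04)
  # no SNR effect generated -> none detected
  expect_gt(est["snr", "p"], 0.01)
})

test_that("baseline-corrected sensitivity: identity and sign pattern", {
  d <- make_choice_data(n_subjects = 10, n_per_cell = 30, seed = 3)
  sdt <- compute_sdt(d)
  bd <- baseline_delta_dprime(sdt)
  expect_lt(max(abs(bd$means)), 0.25)       # same generator both conditions
  # collapsing order (deviation then snr) equals direct cell averaging
  cg <- sdt[sdt$congruency == "congruent", ]
  direct <- tapply(cg$dprime, cg$snr, mean)
  backed_out <- rowMeans(bd$delta_dprime) +
    mean(tapply(sdt$dprime[sdt$congruency == "incongruent"],
                sdt$subject[sdt$congruency == "incongruent"], mean))
  expect_equal(as.numeric(backed_out), as.numeric(direct), tolerance = 0.05)
  # attraction after decision-only trials lowers sensitivity, repulsion
  # after strong stimuli raises it: d-prime change negative at snr 0,
  # positive at snr 75
  d2 <- make_choice_data(n_subjects = 12, n_per_cell = 50, seed = 4,
                         slope_mod = c(congruent_0 = -0.02,
                                       congruent_75 = 0.02))
  bd2 <- baseline_delta_dprime(compute_sdt(d2))
  expect_lt(bd2$means[["0"]], 0)
  expect_gt(bd2$means[["75"]], 0)
  expect_lt(bd2$extremes_test$p.value, 0.05)
})

test_that("delta-P(vertical) is flat for identical conditions and recovers
           opposite DoG amplitudes", {
  d <- make_choice_data(n_subjects = 10, n_per_cell = 40, seed = 5)
  out <- delta_p_vertical(d, snr_levels = c(0, 75))
  expect_lt(max(abs(out$curve$dp)), 0.12)
  # sensitivity loss after decisions (snr 0), gain after strong stimuli
  # (snr 75): the incongruent-minus-congruent proportion curves take
  # opposite-signed DoG-like shapes
  d2 <- make_choice_data(n_subjects = 12, n_per_cell = 60, seed = 6,
                         slope_mod = c(congruent_0 = -0.025,
                                       congruent_75 = 0.035))
  out2 <- delta_p_vertical(d2, snr_levels = c(0, 75))
  f <- out2$fit
  expect_true(sign(f$alpha0) != sign(f$k0))
  expect_lt(f$p_diff, 0.05)
  # the generator is antisymmetric in deviation, and so is the curve
  cv <- out2$curve
  for (s in c(0, 75)) {
    cs <- cv[cv$snr == s, ]
    plus <- cs$dp[match(c(2, 5, 15), cs$deviation)]
    minus <- cs$dp[match(c(-2, -5, -15), cs$deviation)]
    expect_equal(plus, -minus, tolerance = 0.15)
  }
})

test_that("linear mixed fits reduce to OLS without subject variance and
           refuse collinear history predictors", {
  set.seed(7)
  n <- 600
  d <- data.frame(subject = rep(c("a", "b", "c"), each = n / 3),
                  x = runif(n, -1, 1))
  d$error <- 0.5 * d$x + rnorm(n, 0, 0.3)   # no subject offsets
  f <- fit_linear_mixed(d, response = "error", predictors = "x")
  ols <- lm(error ~ x, d)
  expect_equal(f$coefficients["x", "estimate"], unname(coef(ols)[2]),
               tolerance = 1e-4)
  expect_error(fit_linear_mixed(d, predictors = c("delta_S", "delta_R")),
               "collinear")
})

test_that("zero-slope generator: fixed-effect coverage near the nominal rate", {
  set.seed(8)
  cover <- replicate(40, {
    n <- 200
    d <- data.frame(subject = rep(c("a", "b", "c", "d"), each = n / 4),
                    x = runif(n, -1, 1))
    d$error <- rnorm(n, 0, 0.5) +
      rep(rnorm(4, 0, 0.2), each = n / 4)
    f <- fit_linear_mixed(d, response = "error", predictors = "x")
    abs(f$coefficients["x", "estimate"]) <
      1.96 * f$coefficients["x", "se"]
  })
  expect_gt(mean(cover), 0.85)
})
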