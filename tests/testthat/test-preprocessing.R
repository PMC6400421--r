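test_that("fast RTs remove the trial and its successor", {
  tab <- data.frame(subject = "s1", trial = 1:10,
                    stimulus = seq(0, 90, by = 10),
                    response = seq(0, 90, by = 10),
                    rt_ms = c(2000, 2100, 150, 2050, 1900, 2000, 2100, 1950,
                              2020, 1980))
  out <- filter_trials(tab)
  expect_equal(out$data$trial, c(1, 2, 5, 6, 7, 8, 9, 10))
  expect_equal(out$report$n_removed_rt, 1)
  expect_equal(out$report$n_removed_following, 1)
})

test_that("clean RTs pass untouched and filtering is idempotent", {
  set.seed(2)
  tab <- data.frame(subject = rep(c("a", "b"), each = 50), trial = rep(1:50, 2),
                    stimulus = 10, response = 12,
                    rt_ms = rnorm(100, 2000, 100))
  out <- filter_trials(tab)
  expect_equal(nrow(out$data), 100)
  tab$rt_ms[c(5, 60)] <- 100
  once <- filter_trials(tab)
  twice <- filter_trials(once$data)
  expect_equal(nrow(twice$data), nrow(once$data))
})

test_that("removal matches a brute-force two-pass scan", {
  set.seed(3)
  tab <- data.frame(subject = rep("s", 300), trial = 1:300,
                    stimulus = 0, response = 0,
                    rt_ms = c(rlnorm(290, log(2000), 0.3),
                              runif(5, 50, 190), runif(5, 30000, 60000)))
  tab <- tab[sample(300), ]; tab$trial <- 1:300
  out <- filter_trials(tab)
  # oracle: explicit loop
  rt <- tab$rt_ms
  z <- (rt - mean(rt)) / sd(rt)
  bad <- rt < 200 | abs(z) > 3.5
  drop <- rep(FALSE, 300)
  for (i in 1:300) if (bad[i]) { drop[i] <- TRUE; if (i < 300) drop[i + 1] <- TRUE }
  expect_equal(nrow(out$data), sum(!drop))
})

test_that("Grubbs test removes a gross outlier using the t-based critical value", {
  x <- c(1, 2, 3, 100)
  expect_equal(grubbs_critical(4), 1.4812, tolerance = 1e-4)
  keep <- grubbs_filter(x)
  expect_equal(which(!keep), 4L)
  expect_equal(attr(keep, "n_removed"), 1L)
})

test_that("Grubbs leaves constant and tiny samples alone", {
  expect_true(all(grubbs_filter(rep(5, 10))))
  expect_warning(k <- grubbs_filter(c(1, 2)), "fewer than 3")
  expect_true(all(k))
})

test_that("Grubbs rarely rejects more than one point under the null", {
  set.seed(4)
  removed <- replicate(200, attr(grubbs_filter(rnorm(50)), "n_removed"))
  expect_gte(mean(removed <= 1), 0.95)
})

test_that("a three-sinusoid bias injected by the generator is removed", {
  tab <- make_adjustment_data(n_subjects = 4, n_trials = 500, alpha = 0,
                              sigma = 2, seed = 51,
                              bias = orientation_bias_default(2))
  err_pre <- wrap_delta(tab$response, tab$stimulus)
  out <- residualize_orientation_bias(tab)
  err_post <- wrap_delta(out$data$response, out$data$stimulus)
  expect_lt(sqrt(mean(err_post^2)), 0.6 * sqrt(mean(err_pre^2)))
  expect_true(all(vapply(out$fits, function(f) f$family, "") %in%
                    c("sin3", "poly4")))
  # refitting the bias family on the residuals finds almost nothing
  again <- residualize_orientation_bias(out$data)
  err_again <- wrap_delta(again$data$response, again$data$stimulus)
  expect_equal(sqrt(mean(err_again^2)), sqrt(mean(err_post^2)),
               tolerance = 0.05)
})

test_that("zero-bias data are changed only negligibly by residualization", {
  tab <- make_adjustment_data(n_subjects = 3, n_trials = 400, alpha = 0,
                              sigma = 8, seed = 52)
  out <- residualize_orientation_bias(tab)
  err_pre <- wrap_delta(tab$response, tab$stimulus)
  err_post <- wrap_delta(out$data$response, out$data$stimulus)
  # a 9-parameter fit absorbs ~sd*sqrt(9/n) of pure noise; allow that
  expect_lt(sqrt(mean((err_post - err_pre)^2)), 0.3 * sd(err_pre))
})

test_that("size residualization calibrates the report-vs-truth slope to one", {
  tab <- generate_design(experiment_design("exp8", n_subjects = 6,
                                           n_trials = 400), seed = 6)
  beh <- generate_size_behavior(tab, bias_slope = 1.2, intercept = -0.3,
                                sigma = 0.2, seed = 7)
  out <- residualize_size_bias(beh)
  sl <- coef(lm(response ~ stimulus, out$data))[2]
  expect_gt(sl, 0.97); expect_lt(sl, 1.03)
  err <- out$data$response - out$data$stimulus
  expect_lt(abs(cor(err, out$data$stimulus)), 0.05)
  # unit slope: unchanged up to demeaning
  beh1 <- generate_size_behavior(tab, bias_slope = 1, sigma = 0.2, seed = 8)
  out1 <- residualize_size_bias(beh1)
  d <- (out1$data$response - beh1$response)
  expect_lt(sd(tapply(d, cut(beh1$stimulus, 5), mean)), 0.05)
})

test_that("chance-performance test separates real performance from chance", {
  tab <- make_adjustment_data(n_subjects = 3, n_trials = 200, alpha = 0,
                              sigma = 6, seed = 61)
  p <- chance_performance_test(tab, n_perm = 500, seed = 62)
  expect_true(all(p < 0.001 * 5))   # accurate subjects: all tiny
  # perfect responses: p at the add-one floor
  perf <- transform(tab, response = stimulus)
  pp <- chance_performance_test(perf, n_perm = 500, seed = 63)
  expect_true(all(pp <= 1 / 500 + 1e-9))
  # responses independent of targets: p roughly uniform
  set.seed(64)
  nullp <- replicate(60, {
    d <- data.frame(subject = "s", trial = 1:80,
                    stimulus = runif(80, 0, 180),
                    response = runif(80, 0, 180))
    chance_performance_test(d, n_perm = 99)
  })
  ks <- suppressWarnings(ks.test(nullp, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the full preprocessing pipeline reports what it removed", {
  tab <- make_adjustment_data(n_subjects = 5, n_trials = 300, alpha = 1,
                              sigma = 8, seed = 71, rt_contaminant = 0.03,
                              bias = orientation_bias_default(1))
  out <- preprocess_trials(tab)
  expect_s3_class(out$report, "cleaning_report")
  expect_gt(out$report$n_removed_rt, 0)
  expect_lt(out$report$fraction_removed_total, 0.15)
  expect_equal(length(out$report$residualization), 5)
  # per-subject demeaning leaves ~zero mean errors
  err <- wrap_delta(out$data$response, out$data$stimulus)
  expect_lt(max(abs(tapply(err, out$data$subject, mean))), 0.5)
})
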