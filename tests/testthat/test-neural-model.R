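test_that("tuning response peaks at the preferred orientation and is symmetric", {
  expect_equal(tuning_response(45, 45), 1)
  expect_equal(tuning_response(90, 0, angle_mapping = "double"),
               exp(-2 * 4.68), tolerance = 1e-12)
  d <- seq(1, 60, 7)
  expect_equal(tuning_response(30 + d, 30), tuning_response(30 - d, 30))
})

test_that("gain and adaptation profiles have the right peaks and limits", {
  g <- gain_profile(40, alpha_g = 0.3)
  expect_equal(g[41], 1.3)              # channel tuned to 40 deg
  expect_equal(max(g), g[41])
  expect_equal(unname(gain_profile(40, 0)), rep(1, 180))
  a <- adaptation_profile(40, alpha_g = 0.3)
  expect_equal(a[41], 0.7)
  expect_equal(min(a), a[41])
  expect_equal(unname(adaptation_profile(40, 0)), rep(1, 180))
  # far channels barely affected under the doubled mapping
  gd <- gain_profile(0, 0.3, angle_mapping = "double")
  expect_lt(abs(gd[91] - 1), 0.3 * exp(-2 * 4.68) * 1.01)
  expect_error(adaptation_profile(40, 1.2), "alpha_g")
})

test_that("noise-free decoding is veridical for all 180 orientations (doubled mapping)", {
  dec <- vapply(0:179, function(s) {
    pop <- tuning_response(s, 0:179, angle_mapping = "double")
    decode_orientation(pop, readout = "circular", angle_mapping = "double")
  }, numeric(1))
  expect_equal(wrap_delta(dec, 0:179), rep(0, 180), tolerance = 1e-9)
})

test_that("identity-mapping decode is veridical centrally, biased at the wrap", {
  dec <- vapply(c(60, 90, 120), function(s) {
    pop <- tuning_response(s, 0:179)
    decode_orientation(pop)
  }, numeric(1))
  expect_equal(dec, c(60, 90, 120), tolerance = 0.2)
  edge <- decode_orientation(tuning_response(5, 0:179))
  expect_gt(abs(wrap_delta(edge, 5)), 2)  # systematic edge bias, by design
})

test_that("decoding is invariant to rescaling the weights", {
  set.seed(4)
  pop <- runif(180)
  W <- runif(180)
  expect_equal(decode_orientation(pop, W), decode_orientation(pop, 7 * W))
  expect_equal(decode_orientation(pop, W, readout = "circular"),
               decode_orientation(pop, 7 * W, readout = "circular"))
  expect_error(decode_orientation(rep(0, 180), W), "zero")
})

test_that("circular decode agrees with a brute-force vector-sum oracle", {
  set.seed(5)
  for (i in 1:50) {
    pop <- runif(180); W <- runif(180)
    eff <- pop * W
    num <- 0; den <- 0
    for (j in 0:179) {   # explicit summation oracle
      num <- num + eff[j + 1] * sin(2 * j * pi / 180)
      den <- den + eff[j + 1] * cos(2 * j * pi / 180)
    }
    oracle <- (atan2(num, den) * 90 / pi) %% 180
    expect_equal(decode_orientation(pop, W, readout = "circular",
                                    angle_mapping = "double"),
                 oracle, tolerance = 1e-9)
  }
})

test_that("template weights normalize to one and peak at the report", {
  set.seed(6)
  for (i in 1:20) {
    wj <- template_weights(runif(1, 0, 180), runif(1, 0, 2), runif(1, 1, 60),
                           offset = runif(1, 0.01, 1))
    expect_equal(sum(wj), 1, tolerance = 1e-12)
  }
  expect_equal(template_weights(10, 0, 24.5), rep(1 / 180, 180))
  wj <- template_weights(73.2, 0.5, 24.5)
  expect_equal(which.max(wj) - 1, 73)
})

test_that("weight update follows the decay-plus-template rule", {
  W <- rep(1 / 180, 180)
  wj <- template_weights(90, 0.3, 24.5)
  expect_identical(update_weights(W, wj, FALSE, 0.2), W)
  expect_equal(sum(update_weights(W, wj, TRUE, 0.2)), 0.2 + 1)
  # iterating responses: total weight converges to 1/(1 - decay)
  decay <- 0.3
  for (i in 1:60) W <- update_weights(W, wj, TRUE, decay)
  expect_equal(sum(W), 1 / (1 - decay), tolerance = 1e-8)
})

test_that("with all mechanisms off the simulator reproduces the input", {
  cfg <- simulation_config("two_process", alpha_g = 0, alpha_w = 0,
                           sigma = 0, angle_mapping = "double",
                           readout = "circular")
  st <- list(amp = rep(1, 180), W = rep(1 / 180, 180))
  for (s in c(0, 33, 90, 154)) {
    out <- simulate_trial(s, st, cfg)
    expect_equal(out$response, s, tolerance = 1e-9)
    st <- out$state
  }
})

test_that("gain attracts and adaptation repels (sign of conditional bias)", {
  n <- 4000
  des <- experiment_design("exp1", n_subjects = 1, n_trials = n)
  tab <- generate_design(des, seed = 31)
  for (spec in list(list(model = "gain", sign = +1),
                    list(model = "two_process", sign = -1))) {
    cfg <- simulation_config(spec$model, alpha_g = 0.33, alpha_w = 0,
                             w_decay = 0, sigma = 2)
    out <- run_simulation(tab, cfg, seed = 32)
    pr <- serial_predictors(out)
    f <- fit_dog(pr$delta_S, wrap_delta(pr$response, pr$stimulus),
                 fix_w = 0.05)
    expect_gt(spec$sign * f$alpha0, 0.5)
  }
})

test_that("seeded simulations are bit-reproducible", {
  tab <- generate_design(experiment_design("exp1", n_subjects = 2,
                                           n_trials = 50), seed = 8)
  cfg <- simulation_config("two_process", alpha_g = 0.14)
  a <- run_simulation(tab, cfg, seed = 99)
  b <- run_simulation(tab, cfg, seed = 99)
  expect_identical(a$response, b$response)
})

test_that("sequence trials modulate encoding per stimulus, weights only at report", {
  des <- experiment_design("exp5", n_subjects = 1, n_trials = 400,
                           catch_fraction = 0)
  tab <- generate_design(des, seed = 41)
  seqs <- lapply(tab$sequence_json, jsonlite::fromJSON)
  last_nonrep <- vapply(seqs, function(s) s[5], numeric(1))
  # gain model: attraction to the immediately preceding (nonreported)
  # stimulus, no pull from the previous trial's report
  cfg <- simulation_config("gain", alpha_g = 0.33, sigma = 2)
  out <- run_simulation(tab, cfg, seed = 42)
  err <- wrap_delta(out$response, out$stimulus)
  # remove the decoder's stimulus-locked bias, which otherwise leaks into
  # any predictor of the form (x - stimulus)
  err <- err - ave(err, out$stimulus)
  x_non <- wrap_delta(last_nonrep, out$stimulus)
  f_non <- fit_dog(x_non, err, fix_w = 0.05)
  expect_gt(f_non$alpha0, 0.5)
  prev_resp <- c(NA, out$response[-nrow(out)])
  x_rep <- wrap_delta(prev_resp, out$stimulus)
  f_rep <- fit_dog(x_rep, err, fix_w = 0.05)
  expect_lt(abs(f_rep$alpha0), abs(f_non$alpha0) / 2)
})

test_that("width helper reports both conventions", {
  wd <- beta_to_width(4.68)
  expect_equal(wd$circular_sd, 27.8, tolerance = 0.05)
  expect_equal(beta_to_width(4.68, "double")$fwhh, 31.6, tolerance = 0.05)
  expect_equal(beta_to_width(24.5)$circular_sd, 11.7, tolerance = 0.05)
})
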