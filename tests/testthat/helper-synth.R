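# Shared fixtures, all generated in code.

# small adjustment dataset with known DoG ground truth
make_adjustment_data <- function(n_subjects = 5, n_trials = 200, alpha = 2,
                                 w = 0.05, sigma = 8, seed = 1, ...) {
  des <- experiment_design("exp1", n_subjects = n_subjects,
                           n_trials = n_trials)
  tab <- generate_design(des, seed = seed)
  generate_behavior(tab, ground_truth(alpha = alpha, w = w, sigma = sigma,
                                      ...), seed = seed + 1)
}

# forced-choice dual-task data: p("vertical") is a cumulative normal of the
# signed deviation; sensitivity (the slope) may depend on SNR and, in the
# congruent condition, be raised or lowered to emulate repulsion/attraction
# by the preceding task
make_choice_data <- function(n_subjects = 12, n_per_cell = 30,
                             slope_base = 0.05, snr_effect = 0,
                             slope_mod = c(congruent_0 = 0,
                                           congruent_75 = 0),
                             seed = 1) {
  set.seed(seed)
  devs <- c(-40, -15, -5, -2, 2, 5, 15, 40)
  snrs <- c(0, 25, 75)
  grid <- expand.grid(subject = sprintf("s%02d", seq_len(n_subjects)),
                      congruency = c("congruent", "incongruent"),
                      snr = snrs, deviation = devs,
                      rep = seq_len(n_per_cell), stringsAsFactors = FALSE)
  slope <- slope_base + snr_effect * grid$snr / 75
  c0 <- grid$congruency == "congruent" & grid$snr == 0
  c75 <- grid$congruency == "congruent" & grid$snr == 75
  slope[c0] <- slope[c0] + slope_mod[["congruent_0"]]
  slope[c75] <- slope[c75] + slope_mod[["congruent_75"]]
  p_vert <- pnorm(slope * grid$deviation)
  grid$response_vertical <- runif(nrow(grid)) < p_vert
  grid$rep <- NULL
  grid
}
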