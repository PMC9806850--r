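test_that("generated templates are normalised, decorrelated and deterministic", {
  mont <- fix_montage(64)
  one <- make_templates(mont, 1, seed = 4)
  expect_equal(sum(one$maps), 0, tolerance = 1e-9)
  expect_equal(sum(one$maps^2), 1, tolerance = 1e-9)

  expect_identical(make_templates(mont, 4, seed = 9)$maps,
                   make_templates(mont, 4, seed = 9)$maps)

  tpl <- make_templates(mont, 4, seed = 9)
  r <- abs(tcrossprod(tpl$maps))
  expect_true(all(r[upper.tri(r)] <= 0.7 + 1e-12))
})

test_that("semi-Markov sequences honour degenerate and stochastic dwell laws", {
  # forced A->B->A alternation with fixed dwell (shape -> deterministic)
  tm <- matrix(c(0, 1, 1, 0), 2, 2)
  s <- simulate_state_sequence(2, 100, 125, mean_dwell_ms = 10 * 1000 / 125,
                               dwell_shape = 0, transition_matrix = tm,
                               seed = 1)
  runs <- rle(s$states)
  expect_true(all(runs$lengths[-length(runs$lengths)] == 10))
  expect_true(all(abs(diff(runs$values)) == 1))

  expect_true(all(simulate_state_sequence(1, 50, 125, seed = 2)$states == 1L))

  # law of large numbers: realized mean dwell within 10% over 120 s
  s <- simulate_state_sequence(4, 15000, 125, mean_dwell_ms = 100, seed = 3)
  expect_true(all(s$realized$mean_dwell_ms >= 90 &
                    s$realized$mean_dwell_ms <= 110))
  expect_equal(sum(s$realized$occupancy), 1, tolerance = 1e-12)
})

test_that("synthesised recordings obey the noiseless limit and the SNR contract", {
  mont <- fix_montage(32)
  tpl <- make_templates(mont, 3, seed = 5)
  cfg_inf <- synthetic_config(n_channels = 32, duration_s = 8, snr = 1e12)
  s <- simulate_state_sequence(3, 1000, 125, seed = 5)
  rec <- synthesize_recording(tpl, s$states, mont, cfg_inf, seed = 5)
  r <- abs(colSums((rec$data / rep(sqrt(colSums(rec$data^2)), each = 32)) *
                     t(tpl$maps[s$states, ])))
  expect_true(all(r > 1 - 1e-6))

  cfg <- synthetic_config(n_channels = 32, duration_s = 120, snr = 2)
  parts <- synthesize_recording(tpl,
                                simulate_state_sequence(3, 15000, 125, seed = 6)$states,
                                mont, cfg, seed = 6, return_parts = TRUE)
  ratio <- mean(parts$signal^2) / mean(parts$noise^2)
  expect_equal(ratio, 2, tolerance = 0.05)
})

test_that("scaling the envelope scales the noiseless GFP linearly", {
  f <- fix_exact_recording(n_ch = 16, K = 2, n = 100)
  g1 <- compute_gfp(f$rec)$values
  rec2 <- f$rec
  rec2$data <- rec2$data * 2
  g2 <- compute_gfp(rec2)$values
  expect_equal(g2, 2 * g1, tolerance = 1e-12)
})

test_that("cohort generation is deterministic with coupled covariates", {
  cfg <- synthetic_config(n_channels = 16, duration_s = 10)
  c1 <- simulate_cohort(cfg, 2, 2, seed = 21)
  c2 <- simulate_cohort(cfg, 2, 2, seed = 21)
  expect_identical(c1$recordings[[1]]$data, c2$recordings[[1]]$data)
  expect_identical(c1$covariates, c2$covariates)

  # patients carry E (never F), controls carry F (never E)
  gt <- c1$ground_truth$realized
  expect_true(all(gt$occupancy[gt$class == "E" & gt$group == "control"] == 0))
  expect_true(all(gt$occupancy[gt$class == "F" & gt$group == "patient"] == 0))
  expect_true(all(gt$occupancy[gt$class == "E" & gt$group == "patient"] > 0))

  # occupancies sum to one per subject
  occ_sum <- tapply(gt$occupancy, gt$subject_id, sum)
  expect_equal(as.numeric(occ_sum), rep(1, 4), tolerance = 1e-12)

  # coverage/occurrence/duration identity on the generative sequences
  with(gt[!gt$occupancy == 0, ], expect_equal(
    occupancy * 100, occurrence_per_min * mean_dwell_ms / 600,
    tolerance = 1e-9))
})

test_that("covariates track generative parameters at the configured strength", {
  # noiseless coupling limit: SDMT correlates perfectly with class-A occupancy
  cfg <- synthetic_config(n_channels = 16, duration_s = 30,
                          covariate_model = list(sdmt_beta0 = 57,
                                                 sdmt_beta1 = 150,
                                                 sdmt_r2 = 1 - 1e-9,
                                                 dd_mean = 6, dd_sd = 4,
                                                 dd_r2 = 0.1))
  coh <- simulate_cohort(cfg, 6, 6, seed = 31)
  occ_A <- with(coh$ground_truth$realized,
                occupancy[class == "A"])
  expect_gt(cor(coh$covariates$SDMT, occ_A), 0.999)
})
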