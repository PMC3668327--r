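# hypnogram, signal, and cohort generators

test_that("parameter validation rejects infeasible settings", {
  occ <- BASELINE_OCCUPANCY
  occ[1, ] <- c(0.5, 0.4, 0.2) # sums to 1.1
  expect_error(sim_params(phase_occupancy = occ), "sum to 1")
  expect_error(sim_params(dwell_means = c(WAKE = 0.5, NREMS = 20, REMS = 15)),
               ">= 1 epoch")
  expect_error(sim_params(emg_levels = c(WAKE = 1, NREMS = 1, REMS = 0.8)),
               "WAKE emg_level")
  expect_error(cohort_params(rho_rems_asr = 1.2), "correlations")
  expect_error(cohort_params(rems_shock_effect = 0.8), "rems_shock_effect")
  expect_error(cohort_params(n_per_group = 1), "n_per_group")
})

test_that("degenerate occupancy yields an all-WAKE hypnogram", {
  occ <- matrix(rep(c(1, 0, 0), each = 4), nrow = 4)
  sp <- sim_params(phase_occupancy = occ)
  h <- simulate_hypnogram(sp, n_days = 1)
  expect_true(all(h$states == "WAKE"))
})

test_that("simulated occupancy matches the configured stationary target", {
  sp <- sim_params(seed = 5)
  h <- simulate_hypnogram(sp, n_days = 1)
  expect_length(h, 21600)
  slices <- split_phases(h)
  # sampling error of a phase occupancy: bouts of mean length m give an
  # effective sample of N/m, so SE ~ sqrt(2 p (1-p) m / N); the 3-SE band
  # keeps the joint test over 9 cells away from routine excursions
  for (ph in c("II", "III", "IV")) {
    occ <- state_occupancy(slices[[ph]], merge_ma = TRUE) / 100
    for (s in SIM_STATES) {
      p <- sp$phase_occupancy[ph, s]
      m <- sp$dwell_means[s]
      se <- sqrt(2 * p * (1 - p) * m / 5400)
      expect_lt(abs(occ[s] - p), max(3 * se, 0.006),
                label = sprintf("|occ - target| for %s in phase %s", s, ph))
    }
  }
  # and the law-of-large-numbers version: over 10 days the same cells sit
  # within a 1/sqrt(10)-shrunken band
  h10 <- simulate_hypnogram(sp, n_days = 10, seed = 6)
  st <- as.character(h10$states); st[st == "MA"] <- "WAKE"
  phase_of <- rep(rep(c("I", "II", "III", "IV"), each = 5400), 10)
  for (ph in c("II", "III", "IV")) {
    for (s in SIM_STATES) {
      p <- sp$phase_occupancy[ph, s]
      m <- sp$dwell_means[s]
      se <- sqrt(2 * p * (1 - p) * m / (10 * 5400))
      expect_lt(abs(mean(st[phase_of == ph] == s) - p), max(3 * se, 0.004))
    }
  }
})

test_that("hypnogram simulation is deterministic given the seed", {
  sp <- sim_params(seed = 99)
  h1 <- simulate_hypnogram(sp, n_days = 1)
  h2 <- simulate_hypnogram(sp, n_days = 1)
  expect_identical(h1$states, h2$states)
  h3 <- simulate_hypnogram(sp, n_days = 1, seed = 100)
  expect_false(identical(h1$states, h3$states))
})

test_that("NREMS epochs are delta-dominant and REMS epochs theta-dominant", {
  sp <- sim_params(seed = 3)
  hn <- flat_hypnogram("NREMS", 450)
  feats_n <- composite_features(epoch_spectra(synthesize_signals(hn, sp)))
  expect_gte(mean(feats_n$delta > feats_n$theta), 0.95)

  hr <- flat_hypnogram("REMS", 450)
  feats_r <- composite_features(epoch_spectra(synthesize_signals(hr, sp)))
  expect_gt(mean(log(feats_r$theta_comp)), mean(log(feats_n$theta_comp)))
  expect_lt(mean(log(feats_r$delta_comp)), mean(log(feats_n$delta_comp)))

  hw <- flat_hypnogram("WAKE", 450)
  feats_w <- composite_features(epoch_spectra(synthesize_signals(hw, sp)))
  expect_lt(mean(feats_r$emg_rms), mean(feats_w$emg_rms))
  expect_lt(mean(feats_n$emg_rms), mean(feats_w$emg_rms))
})

test_that("zero-amplitude band profile gives a flat EEG", {
  sp <- sim_params(seed = 2)
  zero <- c(delta = 0, theta = 0, alpha = 0, eta = 0, beta = 0)
  sp$band_profiles <- list(WAKE = zero, NREMS = zero, REMS = zero)
  h <- flat_hypnogram("NREMS", 30)
  rec <- synthesize_signals(h, sp)
  expect_equal(max(abs(rec$eeg)), 0)
  feats <- epoch_spectra(rec)
  expect_true(all(as.matrix(feats[, names(EEG_BANDS)]) == 0))
})

test_that("signal synthesis matches the hypnogram grid and seed", {
  sp <- sim_params(seed = 8)
  h <- flat_hypnogram("WAKE", 45)
  rec <- synthesize_signals(h, sp)
  expect_length(rec$eeg, 45 * 256)
  expect_identical(rec$eeg, synthesize_signals(h, sp)$eeg)
  hbad <- flat_hypnogram("WAKE", 45)
  hbad$epoch_len <- 8
  expect_error(synthesize_signals(hbad, sp), "epoch length")
})

test_that("null trait correlation is centered on zero over replicates", {
  rs <- sapply(1:20, function(i) {
    co <- simulate_cohort(cohort_params(n_per_group = 50, rho_rems_asr = 0,
                                        rho_trans_asr = 0, seed = 1000 + i))
    sh <- co$table[co$table$group == "shocked", ]
    cor(sh$baseline_rems_episodes, sh$asr_115)
  })
  expect_lt(abs(mean(rs)), 2 * 1 / sqrt(50) / sqrt(20) + 0.02)
})

test_that("perfect trait correlation gives a near-linear episode/ASR relation", {
  co <- simulate_cohort(cohort_params(n_per_group = 200, rho_rems_asr = 1,
                                      rho_trans_asr = 1,
                                      rho_episodes_trans = 1, seed = 4))
  sh <- co$table[co$table$group == "shocked", ]
  # only integer rounding of the episode count keeps r below 1
  expect_gt(cor(sh$baseline_rems_episodes, sh$asr_115), 0.995)
})

test_that("sample correlations are unbiased for the configured rho", {
  rs <- t(sapply(1:200, function(i) {
    co <- simulate_cohort(cohort_params(n_per_group = 50, seed = 5000 + i))
    sh <- co$table[co$table$group == "shocked", ]
    c(cor(sh$baseline_rems_episodes, sh$asr_115),
      cor(sh$baseline_nrems_to_rems_transitions, sh$asr_115))
  }))
  # E[r] = rho - rho (1 - rho^2) / (2n) + O(n^-2); bias < 0.004 at n = 50
  expect_lt(abs(mean(rs[, 1]) - 0.78), 0.015)
  expect_lt(abs(mean(rs[, 2]) - 0.80), 0.015)
})

test_that("an impossible correlation matrix is rejected", {
  expect_error(
    simulate_cohort(cohort_params(rho_rems_asr = 0.9, rho_trans_asr = -0.9,
                                  rho_episodes_trans = 0.95)),
    "positive semi-definite")
})

test_that("cohort simulation is deterministic and freezing is independent of sleep traits", {
  cp <- cohort_params(n_per_group = 400, seed = 11)
  co1 <- simulate_cohort(cp)
  co2 <- simulate_cohort(cp)
  expect_identical(co1$table, co2$table)
  sh <- co1$table[co1$table$group == "shocked", ]
  expect_lt(abs(cor(sh$baseline_rems_episodes, sh$freezing_chamber)), 0.12)
})
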