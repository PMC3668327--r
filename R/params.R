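#' Vigilance states used throughout the package
#'
#' Four-state alphabet for scored hypnograms; ground-truth simulation uses the
#' three behavioural states (WAKE, NREMS, REMS) and microarousals (MA) arise
#' from the run-length relabelling rule.
#' @export
VIGILANCE_STATES <- c("WAKE", "MA", "NREMS", "REMS")

#' Three-state alphabet (MA merged into WAKE)
#' @export
SIM_STATES <- c("WAKE", "NREMS", "REMS")

#' EEG analysis frequency bands (Hz)
#'
#' delta 0.5-5, theta 6-9, alpha 10-15, eta 16-22.5, beta 23-31.75 Hz.
#' The 5-6 and 9-10 Hz gaps belong to no band.
#' @export
EEG_BANDS <- list(
  delta = c(0.5, 5),
  theta = c(6, 9),
  alpha = c(10, 15),
  eta   = c(16, 22.5),
  beta  = c(23, 31.75)
)

#' Pooled baseline vigilance-state occupancies per Zeitgeber phase
#'
#' Sample-size-weighted pooled means of the two experimental groups
#' (non-shocked n = 7, shocked n = 8). NREMS and REMS take the pooled
#' reported percentages; WAKE is their complement, so it absorbs microarousal
#' time and rounding (the reported per-phase percentages do not always sum to
#' 100). With this convention the pooled circadian summaries come out at
#' their reported values: dark-phase WAKE ~77.3%, light-phase NREMS ~65.4%,
#' light-phase REMS ~8.5%. Phases I/II are the dark (active) period, III/IV
#' the light (inactive) period, each 6 h.
#'
#' @format A 4 x 3 matrix, rows phases I-IV, columns WAKE/NREMS/REMS.
#' @export
BASELINE_OCCUPANCY <- local({
  n1 <- 7; n2 <- 8
  pool <- function(a, b) (n1 * a + n2 * b) / (n1 + n2) / 100
  m <- rbind(
    I   = c(NA, pool(16.4, 10.3), pool(0.6, 0.2)),
    II  = c(NA, pool(30.0, 30.0), pool(2.3, 1.6)),
    III = c(NA, pool(63.6, 66.4), pool(8.5, 9.1)),
    IV  = c(NA, pool(65.9, 65.5), pool(8.9, 7.6))
  )
  m[, 1] <- 1 - m[, 2] - m[, 3]
  colnames(m) <- SIM_STATES
  m
})

default_band_profiles <- function() {
  list(
    WAKE  = c(delta = 0.8, theta = 1.2, alpha = 1.0, eta = 0.8, beta = 0.8),
    NREMS = c(delta = 4.0, theta = 1.0, alpha = 0.8, eta = 0.4, beta = 0.3),
    REMS  = c(delta = 0.5, theta = 3.0, alpha = 0.6, eta = 0.5, beta = 0.4)
  )
}

#' Simulation parameters for synthetic hypnograms and signals
#'
#' Bundles the generator's circadian, spectral and electromyographic settings.
#' Defaults are calibrated to the pooled baseline occupancies
#' ([BASELINE_OCCUPANCY]) and to state-conditional spectral profiles that give
#' delta-dominant NREMS, theta-dominant REMS and high-EMG WAKE.
#'
#' @param sampling_rate Sampling rate in Hz (default 64).
#' @param epoch_len Scoring epoch length in seconds (default 4).
#' @param phase_occupancy 4 x 3 matrix of target time fractions (rows = phases
#'   I-IV, columns WAKE/NREMS/REMS); each row must sum to 1.
#' @param dwell_means Named numeric vector of mean bout lengths in epochs for
#'   WAKE/NREMS/REMS; all >= 1.
#' @param band_profiles Named list (per state) of relative power weights over
#'   the five analysis bands.
#' @param emg_levels Named numeric vector of per-state EMG RMS scales; WAKE
#'   must exceed both sleep states.
#' @param seed Integer seed controlling all randomness downstream.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(sampling_rate = 64,
                       epoch_len = 4,
                       phase_occupancy = BASELINE_OCCUPANCY,
                       dwell_means = c(WAKE = 25, NREMS = 20, REMS = 15),
                       band_profiles = default_band_profiles(),
                       emg_levels = c(WAKE = 4, NREMS = 1, REMS = 0.8),
                       seed = 1L) {
  if (is.matrix(phase_occupancy)) {
    if (!is.null(colnames(phase_occupancy)))
      phase_occupancy <- phase_occupancy[, SIM_STATES, drop = FALSE]
    dimnames(phase_occupancy) <- list(c("I", "II", "III", "IV"), SIM_STATES)
  }
  p <- structure(
    list(
      sampling_rate = sampling_rate, epoch_len = epoch_len,
      phase_occupancy = phase_occupancy, dwell_means = dwell_means,
      band_profiles = band_profiles, emg_levels = emg_levels,
      seed = as.integer(seed)
    ),
    class = "sim_params"
  )
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  occ <- p$phase_occupancy
  if (!is.matrix(occ) || nrow(occ) != 4 || ncol(occ) != 3)
    stop("phase_occupancy must be a 4 x 3 matrix (phases I-IV x WAKE/NREMS/REMS)")
  if (any(occ < 0) || any(occ > 1))
    stop("occupancy fractions must lie in [0, 1]")
  if (any(abs(rowSums(occ) - 1) > 1e-9))
    stop("occupancy fractions must sum to 1 within 1e-9 in every phase")
  dw <- p$dwell_means[SIM_STATES]
  if (anyNA(dw) || any(dw < 1))
    stop("dwell_means must be given for WAKE/NREMS/REMS and be >= 1 epoch")
  emg <- p$emg_levels[SIM_STATES]
  if (anyNA(emg) || any(emg <= 0))
    stop("emg_levels must be strictly positive for all three states")
  if (emg["WAKE"] <= emg["NREMS"] || emg["WAKE"] <= emg["REMS"])
    stop("WAKE emg_level must exceed NREMS and REMS levels")
  for (s in SIM_STATES) {
    bp <- p$band_profiles[[s]]
    if (is.null(bp) || anyNA(bp[names(EEG_BANDS)]) || any(bp < 0))
      stop("band_profiles must give non-negative weights for all five bands per state")
  }
  if (p$sampling_rate <= 2 * 31.75)
    stop("sampling_rate must exceed twice the highest band edge (31.75 Hz)")
  if (p$epoch_len <= 0) stop("epoch_len must be positive")
  invisible(p)
}

#' Cohort-simulation parameters for the trauma study
#'
#' Controls the latent-trait structure linking baseline phase-IV REMS
#' continuity (episode counts, NREMS-to-REMS transitions) to the post-trauma
#' acoustic startle response, the shock-induced phase-IV REMS elevation, and
#' its day-1/day-55 persistence.
#'
#' @param n_per_group Animals per group (>= 2).
#' @param rho_rems_asr Target correlation between baseline phase-IV REMS
#'   episode count and 115-dB ASR in the shocked group (default 0.78).
#' @param rho_trans_asr Target correlation between baseline NREMS-to-REMS
#'   transition count and 115-dB ASR in the shocked group (default 0.80).
#' @param rho_controls Same correlations for the non-shocked group (default 0).
#' @param rho_episodes_trans Latent correlation between episode and transition
#'   counts (default 0.95; the two counts describe nearly the same events).
#' @param rems_shock_effect Multiplicative phase-IV REMS elevation on days
#'   0/1/55 for shocked animals (>= 1; default 1.5).
#' @param persistence_rho Correlation between day-1 and day-55 REMS changes
#'   (default `sqrt(0.54)` so the squared correlation is 0.54).
#' @param episode_mean,episode_sd Baseline phase-IV REMS episode-count
#'   dispersion across animals.
#' @param trans_mean,trans_sd Baseline NREMS-to-REMS transition-count
#'   dispersion.
#' @param asr_mean Named per-group mean 115-dB startle amplitude (arbitrary
#'   voltage units).
#' @param asr_noise_sd Between-animal ASR standard deviation.
#' @param rems_change_sd Between-animal SD of baseline-normalized REMS change
#'   (percentage points).
#' @param freezing_params List of per-context mean freezing percentages for
#'   each group and a common SD.
#' @param seed Integer seed.
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(n_per_group = 8,
                          rho_rems_asr = 0.78,
                          rho_trans_asr = 0.80,
                          rho_controls = 0,
                          rho_episodes_trans = 0.95,
                          rems_shock_effect = 1.5,
                          persistence_rho = sqrt(0.54),
                          episode_mean = 30, episode_sd = 6,
                          trans_mean = 28, trans_sd = 6,
                          asr_mean = c(non_shocked = 350, shocked = 500),
                          asr_noise_sd = 120,
                          rems_change_sd = 15,
                          freezing_params = list(
                            mean = rbind(
                              non_shocked = c(cylinder = 8, tone = 10, hexagon = 18, chamber = 20),
                              shocked     = c(cylinder = 20, tone = 25, hexagon = 30, chamber = 55)
                            ),
                            sd = 12
                          ),
                          seed = 1L) {
  p <- structure(
    list(
      n_per_group = as.integer(n_per_group),
      rho_rems_asr = rho_rems_asr, rho_trans_asr = rho_trans_asr,
      rho_controls = rho_controls, rho_episodes_trans = rho_episodes_trans,
      rems_shock_effect = rems_shock_effect, persistence_rho = persistence_rho,
      episode_mean = episode_mean, episode_sd = episode_sd,
      trans_mean = trans_mean, trans_sd = trans_sd,
      asr_mean = asr_mean, asr_noise_sd = asr_noise_sd,
      rems_change_sd = rems_change_sd, freezing_params = freezing_params,
      seed = as.integer(seed)
    ),
    class = "cohort_params"
  )
  validate_cohort_params(p)
  p
}

validate_cohort_params <- function(p) {
  stopifnot(inherits(p, "cohort_params"))
  rhos <- c(p$rho_rems_asr, p$rho_trans_asr, p$rho_controls,
            p$rho_episodes_trans, p$persistence_rho)
  if (any(abs(rhos) > 1)) stop("all correlations must lie in [-1, 1]")
  if (p$rems_shock_effect < 1)
    stop("rems_shock_effect must be >= 1 for the shocked group")
  if (p$n_per_group < 2) stop("n_per_group must be >= 2")
  if (any(c(p$episode_sd, p$trans_sd, p$asr_noise_sd, p$rems_change_sd) < 0))
    stop("dispersion parameters must be non-negative")
  invisible(p)
}
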