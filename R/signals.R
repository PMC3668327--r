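#' Construct a two-channel EEG/EMG recording
#'
#' @param eeg,emg Numeric amplitude series (arbitrary units, nominally uV),
#'   same length, sampled on a common clock.
#' @param sampling_rate Sampling rate in Hz; must exceed twice the highest
#'   analysis band edge (31.75 Hz).
#' @param zeitgeber_offset Zeitgeber hour of sample 1, in [0, 24).
#' @return Object of class `recording`.
#' @export
recording <- function(eeg, emg, sampling_rate = 64, zeitgeber_offset = 0) {
  if (length(eeg) != length(emg))
    stop("eeg and emg must have the same length")
  if (sampling_rate <= 2 * 31.75)
    stop("sampling_rate must exceed 63.5 Hz (twice the highest band edge)")
  if (zeitgeber_offset < 0 || zeitgeber_offset >= 24)
    stop("zeitgeber_offset must lie in [0, 24)")
  structure(
    list(eeg = as.numeric(eeg), emg = as.numeric(emg),
         sampling_rate = sampling_rate,
         zeitgeber_offset = zeitgeber_offset),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording: %d samples @ %g Hz (%.2f h), ZT offset %g>\n",
              length(x$eeg), x$sampling_rate,
              length(x$eeg) / x$sampling_rate / 3600, x$zeitgeber_offset))
  invisible(x)
}

#' Duration of a recording in hours
#' @param rec A `recording`.
#' @export
recording_duration <- function(rec) length(rec$eeg) / rec$sampling_rate / 3600

# indices (into the 0..N/2 frequency grid, 1-based on k = 0..N/2) of the
# bins inside each band, inclusive of boundary bins
band_bins <- function(freqs) {
  lapply(EEG_BANDS, function(b) which(freqs >= b[1] & freqs <= b[2]))
}

#' Synthesize state-conditional EEG/EMG signals for a hypnogram
#'
#' EEG epochs are built in the frequency domain: each analysis band receives
#' complex Gaussian spectral amplitudes with total expected power equal to the
#' state's band-profile weight (bins outside the five bands stay empty), and
#' the epoch signal is the real inverse FFT. The EMG is white Gaussian noise
#' with the state's RMS scale. Epochs are generated independently; the result
#' is reproducible given the seed.
#'
#' @param hyp A `hypnogram` (MA epochs use the WAKE profile).
#' @param params A [sim_params()] object.
#' @param seed Optional seed override (defaults to `params$seed + 1`).
#' @return A `recording` spanning exactly the hypnogram's epoch grid.
#' @export
synthesize_signals <- function(hyp, params, seed = NULL) {
  validate_sim_params(params)
  if (!inherits(hyp, "hypnogram")) stop("hyp must be a hypnogram")
  n_ep <- length(hyp)
  if (n_ep == 0) stop("hypnogram is empty")
  if (hyp$epoch_len != params$epoch_len)
    stop("hypnogram epoch length does not match params$epoch_len")
  set.seed(if (is.null(seed)) params$seed + 1L else seed)

  n <- as.integer(params$sampling_rate * params$epoch_len) # samples per epoch
  freqs <- (0:(n %/% 2)) / params$epoch_len
  bins <- band_bins(freqs)

  # per-state spectral sd template over the half-spectrum
  states3 <- as.character(hyp$states)
  states3[states3 == "MA"] <- "WAKE"
  sd_tmpl <- sapply(SIM_STATES, function(s) {
    w <- params$band_profiles[[s]]
    tmpl <- numeric(length(freqs))
    for (b in names(EEG_BANDS)) {
      idx <- bins[[b]]
      if (length(idx)) tmpl[idx] <- sqrt(w[[b]] / length(idx))
    }
    tmpl
  })

  nyq <- n %/% 2 + 1L
  half <- matrix(0 + 0i, nrow = nyq, ncol = n_ep)
  sdm <- sd_tmpl[, match(states3, SIM_STATES), drop = FALSE]
  z <- complex(real = stats::rnorm(nyq * n_ep), imaginary = stats::rnorm(nyq * n_ep))
  half[] <- matrix(z, nyq, n_ep) * sdm / sqrt(2)
  half[1, ] <- 0 + 0i          # no DC
  half[nyq, ] <- complex(real = Re(half[nyq, ]) * sqrt(2), imaginary = 0)
  full <- rbind(half, Conj(half[(nyq - 1):2, , drop = FALSE]))
  eeg <- Re(stats::mvfft(full, inverse = TRUE)) / sqrt(n)
  dim(eeg) <- NULL

  emg_sd <- params$emg_levels[states3]
  emg <- stats::rnorm(n * n_ep) * rep(emg_sd, each = n)

  recording(eeg, emg, sampling_rate = params$sampling_rate,
            zeitgeber_offset = hyp$zeitgeber_start)
}
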