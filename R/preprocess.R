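#' Band-pass filter the EEG channel
#'
#' Applies an eight-pole Butterworth band-pass (0.5-29 Hz, roll-off at least
#' 48 dB/octave) forward and backward (zero phase, so epoch boundaries are not
#' smeared by group delay). The EMG channel is left untouched: RMS is always
#' computed on the unfiltered EMG.
#'
#' @param rec A `recording`.
#' @param band Passband edges in Hz (default `c(0.5, 29)`).
#' @return A `recording` with filtered EEG.
#' @export
bandpass_eeg <- function(rec, band = c(0.5, 29)) {
  if (!inherits(rec, "recording")) stop("rec must be a recording")
  nyq <- rec$sampling_rate / 2
  flt <- signal::butter(4, band / nyq, type = "pass")
  warmup <- 3 * (length(flt$a) - 1)
  if (length(rec$eeg) <= warmup)
    stop("recording shorter than the filter warm-up length (",
         warmup, " samples)")
  rec$eeg <- signal::filtfilt(flt, rec$eeg)
  rec
}

#' One-sided periodogram of one epoch
#'
#' Plain FFT on the epoch (rectangular window, no overlap), returned as a
#' one-sided power spectral density in AU^2/Hz on the 1/epoch_len Hz grid so
#' that a trapezoid-rule integral over a frequency interval yields band power
#' in AU^2. The DC bin is excluded (set to zero).
#'
#' @param x Numeric epoch samples.
#' @param fs Sampling rate in Hz.
#' @return List with `freq` (Hz) and `psd` (AU^2/Hz).
#' @export
epoch_periodogram <- function(x, fs) {
  n <- length(x)
  X <- stats::fft(x)
  half <- 1:(n %/% 2 + 1)
  psd <- (Mod(X[half])^2) / (n * fs)
  psd[2:(n %/% 2)] <- 2 * psd[2:(n %/% 2)]
  psd[1] <- 0
  list(freq = (half - 1) * fs / n, psd = psd)
}

#' Trapezoid-rule band power of a power spectrum
#'
#' Integrates a power spectral density over one analysis band with the
#' trapezoid rule, including the boundary frequency bins (half-open gaps
#' between bands belong to no band).
#'
#' @param freq Frequency grid in Hz (ascending).
#' @param psd Power spectral density values (AU^2/Hz) on `freq`.
#' @param band Band name (delta/theta/alpha/eta/beta) or a `c(low, high)`
#'   Hz interval.
#' @return Band power in AU^2.
#' @export
band_auc <- function(freq, psd, band) {
  if (is.character(band)) band <- EEG_BANDS[[match.arg(band, names(EEG_BANDS))]]
  idx <- which(freq >= band[1] & freq <= band[2])
  if (length(idx) < 2) return(0)
  pracma::trapz(freq[idx], psd[idx])
}

#' Per-epoch band powers and EMG RMS
#'
#' Cuts the recording into consecutive 4-s epochs (a trailing partial epoch is
#' dropped with a message), computes the periodogram of each 256-sample EEG
#' window at 0.25 Hz resolution, integrates it over the five analysis bands
#' with the trapezoid rule (band-edge bins inclusive; the 5-6 and 9-10 Hz
#' gaps belong to no band), and computes the RMS of the raw EMG over the same
#' window.
#'
#' @param rec A `recording` (EEG normally already band-passed).
#' @param epoch_len Epoch length in seconds (default 4).
#' @return A data.frame with one row per epoch: `epoch_index` (0-based),
#'   `zeitgeber_hour`, the five band powers, and `emg_rms`.
#' @export
epoch_spectra <- function(rec, epoch_len = 4) {
  if (!inherits(rec, "recording")) stop("rec must be a recording")
  n <- as.integer(rec$sampling_rate * epoch_len)
  n_ep <- length(rec$eeg) %/% n
  if (n_ep == 0) stop("recording shorter than one epoch")
  dropped <- length(rec$eeg) - n_ep * n
  if (dropped > 0)
    message("dropping trailing partial epoch (", dropped, " samples)")

  eeg <- matrix(rec$eeg[seq_len(n_ep * n)], nrow = n)
  emg <- matrix(rec$emg[seq_len(n_ep * n)], nrow = n)

  X <- stats::mvfft(eeg)
  half <- 1:(n %/% 2 + 1)
  psd <- (Mod(X[half, , drop = FALSE])^2) / (n * rec$sampling_rate)
  psd[2:(n %/% 2), ] <- 2 * psd[2:(n %/% 2), , drop = FALSE]
  psd[1, ] <- 0
  freqs <- (half - 1) * rec$sampling_rate / n

  bands <- sapply(names(EEG_BANDS), function(b)
    apply(psd, 2, function(col) band_auc(freqs, col, b)))
  colnames(bands) <- names(EEG_BANDS)

  data.frame(
    epoch_index = seq_len(n_ep) - 1L,
    zeitgeber_hour = (rec$zeitgeber_offset +
                        (seq_len(n_ep) - 1) * epoch_len / 3600) %% 24,
    bands,
    emg_rms = sqrt(colMeans(emg^2))
  )
}

#' Composite delta and theta staging features
#'
#' Adds the composite features that sharpen the NREMS/REMS contrast:
#' `delta_comp` = (delta x alpha) / (eta x beta) and
#' `theta_comp` = theta^2 / (delta x alpha). Epochs with a zero denominator
#' are flagged `indeterminate` and get NA composites (excluded from threshold
#' fitting; the classifier carries the previous label over them).
#'
#' @param features Data.frame from [epoch_spectra()].
#' @return The same data.frame with `delta_comp`, `theta_comp`,
#'   `indeterminate` columns added.
#' @export
composite_features <- function(features) {
  req <- names(EEG_BANDS)
  if (!all(req %in% names(features)))
    stop("features must contain the five band-power columns")
  den_d <- features$eta * features$beta
  den_t <- features$delta * features$alpha
  ind <- den_d == 0 | den_t == 0
  features$delta_comp <- ifelse(ind, NA_real_,
                                (features$delta * features$alpha) / den_d)
  features$theta_comp <- ifelse(ind, NA_real_, features$theta^2 / den_t)
  features$indeterminate <- ind
  features
}
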