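# Behavioral endpoints of the fear-conditioning assessment: acoustic startle
# amplitudes per stimulus intensity and freezing percentages per context.

#' Startle intensities (dB(A)) of a test session
#' @export
STARTLE_INTENSITIES <- c("control", "75", "90", "105", "115")

#' Freezing test contexts
#' @export
FREEZING_CONTEXTS <- c("cylinder", "tone", "hexagon", "chamber")

#' Startle amplitude of one trial
#'
#' Peak (signed maximum by default) of the response trace within the
#' half-open window of 50 ms after stimulus onset.
#'
#' @param trace Numeric voltage series.
#' @param onset_index Sample index (1-based) of stimulus onset.
#' @param sampling_rate Trace sampling rate in Hz.
#' @param window_ms Response window length (default 50 ms).
#' @param absolute Use the maximum absolute value instead of the signed
#'   maximum.
#' @return Peak amplitude.
#' @export
startle_amplitude <- function(trace, onset_index, sampling_rate,
                              window_ms = 50, absolute = FALSE) {
  n_win <- floor(sampling_rate * window_ms / 1000)
  if (n_win < 1) stop("window shorter than one sample")
  last <- onset_index + n_win - 1
  if (onset_index < 1 || last > length(trace))
    stop("trace does not cover ", window_ms, " ms after stimulus onset")
  w <- trace[onset_index:last]
  if (absolute) max(abs(w)) else max(w)
}

#' Per-intensity mean startle amplitudes of a session
#'
#' A session holds 20 trials per startle intensity (75/90/105/115 dB) and 10
#' control trials; the summary is the per-intensity mean amplitude.
#'
#' @param session Data.frame with columns `intensity` (factor or character
#'   over [STARTLE_INTENSITIES]) and `amplitude`.
#' @param n_startle_trials,n_control_trials Expected trial counts (defaults
#'   20 and 10); a mismatch is an error naming the intensity.
#' @return Named numeric vector of mean amplitudes per intensity.
#' @export
asr_summary <- function(session, n_startle_trials = 20, n_control_trials = 10) {
  if (!all(c("intensity", "amplitude") %in% names(session)))
    stop("session must have columns intensity, amplitude")
  intensity <- as.character(session$intensity)
  bad <- setdiff(unique(intensity), STARTLE_INTENSITIES)
  if (length(bad)) stop("unknown intensities: ", paste(bad, collapse = ", "))
  out <- numeric(length(STARTLE_INTENSITIES))
  names(out) <- STARTLE_INTENSITIES
  for (lv in STARTLE_INTENSITIES) {
    sel <- intensity == lv
    want <- if (lv == "control") n_control_trials else n_startle_trials
    if (sum(sel) != want)
      stop("expected ", want, " trials at intensity ", lv, ", found ", sum(sel))
    out[lv] <- mean(session$amplitude[sel])
  }
  out
}

merge_intervals <- function(intervals) {
  if (length(intervals) == 0) return(matrix(numeric(0), ncol = 2))
  m <- matrix(unlist(intervals), ncol = 2, byrow = TRUE)
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  for (i in seq_len(nrow(m))[-1]) {
    if (m[i, 1] <= out[nrow(out), 2]) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], m[i, 2])
    } else {
      out <- rbind(out, m[i, ])
    }
  }
  out
}

#' Percentage of the observation window spent freezing
#'
#' Freezing intervals are merged (overlaps collapse) before the total is
#' expressed as a percentage of the observation window.
#'
#' @param intervals List of `c(start, end)` second pairs, or an n x 2 matrix;
#'   all within `[0, window_s]`.
#' @param window_s Observation window in seconds (default 180, the 3-min
#'   context exposure).
#' @return Percentage in `[0, 100]`.
#' @export
freezing_fraction <- function(intervals, window_s = 180) {
  if (is.matrix(intervals))
    intervals <- split(intervals, row(intervals)[, 1])
  if (length(intervals) == 0) return(0)
  m <- matrix(unlist(intervals), ncol = 2, byrow = TRUE)
  if (any(m[, 2] < m[, 1])) stop("interval end precedes start")
  if (any(m < 0) || any(m > window_s))
    stop("intervals must lie within [0, ", window_s, "]")
  merged <- merge_intervals(intervals)
  100 * sum(merged[, 2] - merged[, 1]) / window_s
}

#' Simulate one startle session for an animal
#'
#' Trial amplitudes are Gaussian around the per-intensity mean response;
#' intensities are interleaved in pseudo-random order as in the test protocol.
#'
#' @param mean_by_intensity Named vector of mean amplitudes over
#'   [STARTLE_INTENSITIES].
#' @param trial_sd Within-animal trial-to-trial SD.
#' @param seed Integer seed.
#' @return Data.frame with `trial`, `intensity`, `amplitude`.
#' @export
simulate_startle_session <- function(mean_by_intensity, trial_sd = 30,
                                     seed = 1L) {
  stopifnot(all(STARTLE_INTENSITIES %in% names(mean_by_intensity)))
  set.seed(seed)
  intensity <- sample(c(rep("control", 10),
                        rep(c("75", "90", "105", "115"), each = 20)))
  amp <- stats::rnorm(length(intensity),
                      mean = mean_by_intensity[intensity], sd = trial_sd)
  data.frame(trial = seq_along(intensity), intensity = intensity,
             amplitude = pmax(amp, 0))
}
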