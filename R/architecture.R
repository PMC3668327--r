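# Sleep composition and architecture per Zeitgeber phase: occupancy,
# episodes, transitions, state-specific band-power AUC, baseline
# normalization.

#' Zeitgeber phase windows
#'
#' Phases I-IV are consecutive 6-h blocks of the 24-h day mapped to half-open
#' hour intervals [0,6), [6,12), [12,18), [18,24): I/II the dark (active)
#' period, III/IV the light (inactive) period.
#' @export
PHASE_WINDOWS <- list(I = c(0, 6), II = c(6, 12), III = c(12, 18), IV = c(18, 24))

#' Split a 24-h hypnogram into Zeitgeber phases
#'
#' @param h A `hypnogram` spanning exactly one 24-h day aligned to
#'   Zeitgeber 0.
#' @param exclude_phase1 Flag phase I as excluded (used on the shock day,
#'   when the animals spent part of phase I outside the recording cage).
#' @return Named list of four `hypnogram` slices, each with attribute
#'   `excluded`.
#' @export
split_phases <- function(h, exclude_phase1 = FALSE) {
  if (!inherits(h, "hypnogram")) stop("h must be a hypnogram")
  if (h$zeitgeber_start != 0)
    stop("hypnogram must be aligned to Zeitgeber 0 (starts at ",
         h$zeitgeber_start, " h)")
  hours <- length(h) * h$epoch_len / 3600
  if (abs(hours - 24) > 1e-9)
    stop("hypnogram must span exactly 24 h (covers ", round(hours, 3), " h)")
  per_phase <- length(h) / 4
  out <- lapply(seq_along(PHASE_WINDOWS), function(i) {
    idx <- ((i - 1) * per_phase + 1):(i * per_phase)
    slice <- hypnogram(as.character(h$states[idx]), epoch_len = h$epoch_len,
                       zeitgeber_start = PHASE_WINDOWS[[i]][1],
                       provenance = h$provenance)
    attr(slice, "excluded") <- (i == 1 && exclude_phase1)
    slice
  })
  names(out) <- names(PHASE_WINDOWS)
  out
}

#' State occupancy of a hypnogram slice
#'
#' @param h A `hypnogram` (typically one phase slice).
#' @param merge_ma Merge MA into WAKE and report 3 states (the circadian
#'   summary convention); default `FALSE` reports all 4 states.
#' @return Named numeric vector of percentages summing to 100.
#' @export
state_occupancy <- function(h, merge_ma = FALSE) {
  if (!inherits(h, "hypnogram") || length(h) == 0)
    stop("h must be a non-empty hypnogram")
  s <- as.character(h$states)
  if (merge_ma) {
    s[s == "MA"] <- "WAKE"
    tab <- table(factor(s, levels = SIM_STATES))
  } else {
    tab <- table(factor(s, levels = VIGILANCE_STATES))
  }
  pct <- 100 * as.vector(tab) / length(s)
  names(pct) <- names(tab)
  pct
}

#' Maximal-run episodes of a hypnogram slice
#'
#' @param h A `hypnogram`.
#' @return Data.frame with `state`, `start_epoch` (1-based), `length_epochs`,
#'   `duration_s`, and `truncated` (touches the slice boundary).
#' @export
find_episodes <- function(h) {
  if (!inherits(h, "hypnogram") || length(h) == 0)
    stop("h must be a non-empty hypnogram")
  r <- rle(as.character(h$states))
  start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  data.frame(
    state = r$values,
    start_epoch = start,
    length_epochs = r$lengths,
    duration_s = r$lengths * h$epoch_len,
    truncated = seq_along(r$values) %in% c(1L, length(r$values))
  )
}

#' Episode count and mean duration per state
#'
#' @param h A `hypnogram`.
#' @return Data.frame with one row per vigilance state: `episode_count`,
#'   `mean_duration_s` (NA for absent states).
#' @export
episode_stats <- function(h) {
  ep <- find_episodes(h)
  out <- data.frame(state = VIGILANCE_STATES, episode_count = 0L,
                    mean_duration_s = NA_real_)
  for (i in seq_along(VIGILANCE_STATES)) {
    sel <- ep$state == VIGILANCE_STATES[i]
    out$episode_count[i] <- sum(sel)
    if (any(sel)) out$mean_duration_s[i] <- mean(ep$duration_s[sel])
  }
  out
}

#' Transition counts between vigilance states
#'
#' Entry (a, b) counts adjacent epoch pairs labelled a then b, a != b;
#' the diagonal is zero by construction.
#'
#' @param h A `hypnogram` of length >= 2.
#' @return 4 x 4 integer matrix over WAKE/MA/NREMS/REMS.
#' @export
transition_counts <- function(h) {
  if (!inherits(h, "hypnogram") || length(h) < 2)
    stop("h must be a hypnogram with at least 2 epochs")
  s <- factor(as.character(h$states), levels = VIGILANCE_STATES)
  n <- length(s)
  tab <- table(from = s[-n], to = s[-1])
  m <- matrix(as.integer(tab), 4, 4,
              dimnames = list(from = VIGILANCE_STATES, to = VIGILANCE_STATES))
  diag(m) <- 0L
  m
}

#' State-specific band-power AUC
#'
#' Mean, over the epochs a state occupies in the slice, of the trapezoid-rule
#' area of the epoch's power spectrum across the band -- i.e. the mean of the
#' per-epoch band power already computed by [epoch_spectra()].
#'
#' @param features Data.frame from [epoch_spectra()], aligned to `h` (same
#'   epoch count and order).
#' @param h The `hypnogram` slice.
#' @param state One of WAKE/MA/NREMS/REMS.
#' @param band One of delta/theta/alpha/eta/beta.
#' @return Mean band power (AU^2), or NA with a warning if the state is
#'   absent from the slice.
#' @export
state_band_auc <- function(features, h, state, band) {
  state <- match.arg(state, VIGILANCE_STATES)
  band <- match.arg(band, names(EEG_BANDS))
  if (nrow(features) != length(h))
    stop("features and hypnogram slice have different epoch counts")
  sel <- as.character(h$states) == state
  if (!any(sel)) {
    warning("state ", state, " absent from slice; AUC undefined")
    return(NA_real_)
  }
  mean(features[[band]][sel])
}

#' Normalize a value to a baseline group mean
#'
#' @param value Numeric value(s).
#' @param baseline_group_mean Baseline group mean (> 0).
#' @return 100 x value / baseline (100 = baseline level); NA with a warning
#'   for a non-positive baseline.
#' @export
normalize_to_baseline <- function(value, baseline_group_mean) {
  if (!is.finite(baseline_group_mean) || baseline_group_mean <= 0) {
    warning("non-positive baseline mean; normalized value undefined")
    return(rep(NA_real_, length(value)))
  }
  100 * value / baseline_group_mean
}

#' Architecture summary of one 24-h hypnogram
#'
#' Tidy per-phase summary: 4-state occupancy, episode counts and mean
#' durations, and counts of transitions into and out of REMS (the continuity
#' parameters used by the biomarker analysis).
#'
#' @param h A 24-h `hypnogram` aligned to Zeitgeber 0.
#' @param exclude_phase1 Passed to [split_phases()].
#' @return Data.frame with columns `phase`, `excluded`, `variable`, `state`,
#'   `value` in long format.
#' @export
architecture_summary <- function(h, exclude_phase1 = FALSE) {
  slices <- split_phases(h, exclude_phase1 = exclude_phase1)
  rows <- list()
  for (ph in names(slices)) {
    sl <- slices[[ph]]
    occ <- state_occupancy(sl)
    est <- episode_stats(sl)
    tm <- transition_counts(sl)
    rows[[ph]] <- rbind(
      data.frame(phase = ph, excluded = attr(sl, "excluded"),
                 variable = "occupancy_pct", state = names(occ),
                 value = as.numeric(occ)),
      data.frame(phase = ph, excluded = attr(sl, "excluded"),
                 variable = "episode_count", state = est$state,
                 value = as.numeric(est$episode_count)),
      data.frame(phase = ph, excluded = attr(sl, "excluded"),
                 variable = "mean_episode_duration_s", state = est$state,
                 value = est$mean_duration_s),
      data.frame(phase = ph, excluded = attr(sl, "excluded"),
                 variable = c("transitions_NREMS_to_REMS",
                              "transitions_REMS_to_WAKE",
                              "transitions_REMS_to_NREMS"),
                 state = "REMS",
                 value = c(tm["NREMS", "REMS"], tm["REMS", "WAKE"],
                           tm["REMS", "NREMS"]))
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
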