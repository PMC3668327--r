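# Threshold-based vigilance-state scoring: WAKE from EMG amplitude, REMS from
# low composite delta plus high composite theta, everything else NREMS, then
# brief WAKE runs relabelled as microarousals.

#' Variance-minimizing two-class split (Otsu criterion)
#'
#' Scans every cut point between consecutive sorted values and returns the
#' threshold maximizing the between-class variance
#' w1*w2*(mu1 - mu2)^2 (equivalently, minimizing within-class variance).
#'
#' @param x Numeric values (non-finite entries dropped).
#' @return The cut value (midpoint between the two straddling observations),
#'   or NA if the input is degenerate (fewer than 2 distinct values).
#' @export
otsu_split <- function(x) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 2 || x[1] == x[n]) return(NA_real_)
  k <- seq_len(n - 1)
  csum <- cumsum(x)
  mu1 <- csum[k] / k
  mu2 <- (csum[n] - csum[k]) / (n - k)
  bcv <- (k / n) * ((n - k) / n) * (mu1 - mu2)^2
  # cuts between tied values are not realizable thresholds
  bcv[x[k] == x[k + 1]] <- -Inf
  j <- which.max(bcv)
  (x[j] + x[j + 1]) / 2
}

#' Staging thresholds
#'
#' @param emg_thr EMG RMS threshold separating movement from no movement.
#' @param delta_thr Composite-delta threshold separating high from low delta
#'   power.
#' @param theta_thr Composite-theta threshold separating high from low theta
#'   power.
#' @param method `"auto"` or `"manual"`.
#' @return Object of class `thresholds`.
#' @export
thresholds <- function(emg_thr, delta_thr, theta_thr,
                       method = c("auto", "manual")) {
  v <- c(emg = emg_thr, delta = delta_thr, theta = theta_thr)
  if (anyNA(v) || any(!is.finite(v)) || any(v <= 0))
    stop("all thresholds must be positive and finite")
  structure(list(emg_thr = emg_thr, delta_thr = delta_thr,
                 theta_thr = theta_thr, method = match.arg(method)),
            class = "thresholds")
}

#' @export
print.thresholds <- function(x, ...) {
  cat(sprintf("<thresholds (%s): emg %.4g, delta' %.4g, theta' %.4g>\n",
              x$method, x$emg_thr, x$delta_thr, x$theta_thr))
  invisible(x)
}

#' Fit staging thresholds automatically
#'
#' Replaces the manual threshold setting of the original scoring procedure
#' with a reproducible rule: each of log(EMG RMS), log(delta'), log(theta')
#' is split by the variance-minimizing (Otsu) criterion over the recording's
#' epochs. A degenerate (effectively unimodal or constant) feature falls back
#' to the median with a warning. Manual values override any subset.
#'
#' @param features Data.frame from [composite_features()] with at least 100
#'   epochs with finite features.
#' @param emg_thr,delta_thr,theta_thr Optional manual overrides.
#' @return A `thresholds` object; `method` is `"auto"` unless every value was
#'   supplied manually.
#' @export
fit_thresholds <- function(features, emg_thr = NULL, delta_thr = NULL,
                           theta_thr = NULL) {
  ok <- is.finite(features$emg_rms) & is.finite(features$delta_comp) &
    is.finite(features$theta_comp)
  if (sum(ok) < 100)
    stop("need at least 100 epochs with finite features to fit thresholds")
  fit1 <- function(x, name) {
    lx <- log(x[ok & x > 0])
    cut <- otsu_split(lx)
    if (!is.na(cut)) {
      # guard against a spurious split of an essentially unstructured
      # distribution: require the split to explain some of the variance
      lo <- lx < cut
      bcv <- mean(lo) * mean(!lo) * (mean(lx[lo]) - mean(lx[!lo]))^2
      if (bcv < 0.5 * stats::var(lx)) cut <- NA_real_
    }
    if (is.na(cut)) {
      warning("degenerate ", name, " distribution; falling back to the median")
      cut <- stats::median(lx)
    }
    exp(cut)
  }
  auto_needed <- is.null(emg_thr) || is.null(delta_thr) || is.null(theta_thr)
  thresholds(
    emg_thr   = if (is.null(emg_thr)) fit1(features$emg_rms, "EMG RMS") else emg_thr,
    delta_thr = if (is.null(delta_thr)) fit1(features$delta_comp, "delta'") else delta_thr,
    theta_thr = if (is.null(theta_thr)) fit1(features$theta_comp, "theta'") else theta_thr,
    method = if (auto_needed) "auto" else "manual"
  )
}

#' Classify epochs into WAKE/NREMS/REMS
#'
#' Rule order per epoch: EMG RMS above the movement threshold gives WAKE;
#' otherwise composite delta below its threshold together with composite
#' theta above its threshold gives REMS; every other sleep epoch is NREMS.
#' Indeterminate-feature epochs inherit the previous epoch's label (a leading
#' indeterminate epoch defaults to NREMS).
#'
#' @param features Data.frame from [composite_features()].
#' @param thr A `thresholds` object.
#' @return A 3-state `hypnogram` with provenance `"scored"`.
#' @export
classify_epochs <- function(features, thr) {
  if (!inherits(thr, "thresholds")) stop("thr must be a thresholds object")
  n <- nrow(features)
  if (n == 0) stop("no epochs to classify")
  ind <- if ("indeterminate" %in% names(features)) features$indeterminate
         else !is.finite(features$delta_comp) | !is.finite(features$theta_comp)
  lab <- ifelse(features$emg_rms > thr$emg_thr, "WAKE",
         ifelse(features$delta_comp < thr$delta_thr &
                features$theta_comp > thr$theta_thr, "REMS", "NREMS"))
  lab[ind] <- NA
  if (is.na(lab[1])) lab[1] <- "NREMS"
  if (anyNA(lab)) {
    for (i in which(is.na(lab))) lab[i] <- lab[i - 1]
  }
  hypnogram(lab, epoch_len = 4,
            zeitgeber_start = if (n > 0) features$zeitgeber_hour[1] else 0,
            provenance = "scored")
}

#' Relabel brief WAKE runs as microarousals
#'
#' Every maximal WAKE run shorter than 3 epochs (12 s) becomes MA; longer
#' runs and sleep states are untouched. Runs truncated by the recording
#' boundary are eligible.
#'
#' @param h A 3-state `hypnogram` (an input already containing MA is an
#'   error; the rule is defined on raw 3-state scores).
#' @return A 4-state `hypnogram`.
#' @export
mark_microarousals <- function(h) {
  if (!inherits(h, "hypnogram")) stop("h must be a hypnogram")
  s <- as.character(h$states)
  if (any(s == "MA")) stop("input hypnogram already contains MA labels")
  r <- rle(s)
  short_wake <- r$values == "WAKE" & r$lengths < 3
  r$values[short_wake] <- "MA"
  h$states <- factor(inverse.rle(r), levels = VIGILANCE_STATES)
  h
}

#' Score a recording end to end
#'
#' Band-pass filter, epoch spectra, composite features, automatic threshold
#' fitting (unless thresholds are supplied), rule-based classification, and
#' microarousal relabelling.
#'
#' @param rec A `recording`.
#' @param thr Optional `thresholds`; fitted automatically when absent.
#' @param verbose Log fitted thresholds and indeterminate-epoch count.
#' @return A 4-state `hypnogram` with attributes `thresholds` and
#'   `n_indeterminate`.
#' @export
score_recording <- function(rec, thr = NULL, verbose = FALSE) {
  if (!inherits(rec, "recording")) stop("rec must be a recording")
  if (length(rec$eeg) == 0) stop("empty recording")
  feats <- composite_features(epoch_spectra(bandpass_eeg(rec)))
  if (is.null(thr)) thr <- fit_thresholds(feats)
  if (verbose)
    message(sprintf("thresholds: emg %.4g, delta' %.4g, theta' %.4g; %d indeterminate epochs",
                    thr$emg_thr, thr$delta_thr, thr$theta_thr,
                    sum(feats$indeterminate)))
  h <- mark_microarousals(classify_epochs(feats, thr))
  attr(h, "thresholds") <- thr
  attr(h, "n_indeterminate") <- sum(feats$indeterminate)
  h
}
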