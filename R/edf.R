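# Minimal European Data Format (EDF) I/O for two-channel EEG/EMG recordings.
# 16-bit samples, one-second data records; enough of the format for
# round-tripping this package's recordings. No annotations, no EDF+.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' Two signals labelled "EEG" and "EMG", 16-bit, one-second data records.
#' Physical scaling spans the observed amplitude range of each channel, so
#' round-trip error is bounded by the 16-bit quantization step.
#'
#' @param rec A `recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  if (!inherits(rec, "recording")) stop("rec must be a recording")
  fs <- rec$sampling_rate
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  n_rec <- length(rec$eeg) %/% fs
  if (n_rec == 0) stop("recording shorter than one EDF data record (1 s)")
  chans <- list(EEG = rec$eeg[seq_len(n_rec * fs)],
                EMG = rec$emg[seq_len(n_rec * fs)])

  pmin <- sapply(chans, function(x) min(x, -1e-6))
  pmax <- sapply(chans, function(x) max(x, 1e-6))
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("synthetic mouse", 80),
    edf_pad(sprintf("ZT-offset %.6f h", rec$zeitgeber_offset), 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + 2), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(1, 8), edf_pad(2, 4)
  )
  sig <- function(vals, width) paste(vapply(vals, edf_pad, "", width), collapse = "")
  hdr <- paste0(
    hdr,
    sig(names(chans), 16), sig(c("", ""), 80), sig(c("uV", "uV"), 8),
    sig(sprintf("%.8g", pmin), 8), sig(sprintf("%.8g", pmax), 8),
    sig(c(dmin, dmin), 8), sig(c(dmax, dmax), 8), sig(c("", ""), 80),
    sig(c(fs, fs), 8), sig(c("", ""), 32)
  )
  writeChar(hdr, con, eos = NULL)

  scale <- (dmax - dmin) / (pmax - pmin)
  dig <- lapply(names(chans), function(ch) {
    d <- round((chans[[ch]] - pmin[ch]) * scale[ch] + dmin)
    matrix(as.integer(pmin(pmax(d, dmin), dmax)), nrow = fs)
  })
  for (r in seq_len(n_rec)) {
    writeBin(dig[[1]][, r], con, size = 2, endian = "little")
    writeBin(dig[[2]][, r], con, size = 2, endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)
  rd(80)
  rec_id <- rd(80)
  rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 2) stop("EDF header unreadable or fewer than 2 signals")
  labels <- toupper(vapply(seq_len(ns), function(i) rd(16), ""))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)

  i_eeg <- match("EEG", labels); i_emg <- match("EMG", labels)
  if (is.na(i_eeg)) stop("missing EEG channel in ", path)
  if (is.na(i_emg)) stop("missing EMG channel in ", path)
  if (spr[i_eeg] != spr[i_emg])
    stop("EEG and EMG sampling rates differ in ", path)

  out <- matrix(0, nrow = n_rec * spr[i_eeg], ncol = 2)
  sel <- c(i_eeg, i_emg)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[i], size = 2,
                   endian = "little", signed = TRUE)
      j <- match(i, sel)
      if (!is.na(j))
        out[((r - 1) * spr[i] + 1):(r * spr[i]), j] <-
          pmin[i] + (d - dmin[i]) * (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
    }
  }
  zt <- 0
  m <- regmatches(rec_id, regexec("ZT-offset ([0-9.]+) h", rec_id))[[1]]
  if (length(m) == 2) zt <- as.numeric(m[2])
  recording(out[, 1], out[, 2], sampling_rate = spr[i_eeg] / rec_dur,
            zeitgeber_offset = zt)
}

#' Read an EEG/EMG recording from disk
#'
#' EDF files must contain channels labelled "EEG" and "EMG"; CSV files need
#' columns `time_s`, `eeg`, `emg`. Recordings sampled at a rate other than
#' `target_rate` are resampled with a polyphase filter and a message is
#' emitted.
#'
#' @param path File path.
#' @param format `"edf"` or `"csv"` (default guessed from the extension).
#' @param target_rate Analysis sampling rate in Hz (default 64).
#' @param zeitgeber_offset Override for the Zeitgeber hour of the first
#'   sample (CSV files carry no metadata; default 0 unless the file does).
#' @return A `recording` at `target_rate` Hz.
#' @export
read_recording <- function(path, format = c("auto", "edf", "csv"),
                           target_rate = 64, zeitgeber_offset = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"

  if (format == "edf") {
    rec <- read_edf(path)
  } else {
    tbl <- utils::read.csv(path)
    for (col in c("time_s", "eeg", "emg"))
      if (!col %in% names(tbl))
        stop("missing ", toupper(sub("_s$", "", col)), " channel/column in ", path)
    fs <- 1 / stats::median(diff(tbl$time_s))
    rec <- recording(tbl$eeg, tbl$emg, sampling_rate = round(fs),
                     zeitgeber_offset = 0)
  }
  if (!is.null(zeitgeber_offset)) rec$zeitgeber_offset <- zeitgeber_offset

  if (rec$sampling_rate != target_rate) {
    frac <- MASS::fractions(target_rate / rec$sampling_rate)
    pq <- as.integer(strsplit(attr(frac, "fracs"), "/")[[1]])
    if (length(pq) == 1) pq <- c(pq, 1L)
    message("resampling from ", rec$sampling_rate, " to ", target_rate,
            " Hz (polyphase ", pq[1], "/", pq[2], ")")
    rec <- recording(signal::resample(rec$eeg, pq[1], pq[2]),
                     signal::resample(rec$emg, pq[1], pq[2]),
                     sampling_rate = target_rate,
                     zeitgeber_offset = rec$zeitgeber_offset)
  }
  rec
}
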