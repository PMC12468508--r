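#' Epoch rejection rules
#'
#' Thresholds used to flag contaminated epochs: excessive raw amplitude
#' (> `amp_max` uV), abnormally fast activity (> `fast_amp` uV in the
#' `fast_band`), and abnormally slow activity (> `slow_amp` uV in the
#' `slow_band`). Band amplitude is half the peak-to-peak of the zero-phase
#' band-filtered trace; the slow-band amplitude is evaluated on the epoch
#' extended symmetrically to 4 s (where available), since a 0-1 Hz criterion
#' is not measurable on a 1 s window alone.
#'
#' @param amp_max Raw amplitude threshold, uV.
#' @param fast_band,slow_band Frequency intervals in Hz.
#' @param fast_amp,slow_amp Band-amplitude thresholds, uV.
#' @param epoch_len Epoch length in seconds.
#' @return An object of class `rejection_rules`.
#' @export
rejection_rules <- function(amp_max = 100, fast_band = c(20, 35),
                            fast_amp = 35, slow_band = c(0, 1),
                            slow_amp = 50, epoch_len = 1) {
  if (amp_max <= 0 || fast_amp <= 0 || slow_amp <= 0)
    stop("thresholds must be > 0")
  if (epoch_len <= 0) stop("epoch_len must be > 0")
  if (diff(fast_band) <= 0 || diff(slow_band) <= 0)
    stop("band intervals must be increasing")
  structure(list(amp_max = amp_max, fast_band = fast_band,
                 fast_amp = fast_amp, slow_band = slow_band,
                 slow_amp = slow_amp, epoch_len = epoch_len),
            class = "rejection_rules")
}

# Zero-phase 4th-order Butterworth band filter; band in Hz, low edge 0 means
# a pure low-pass. Returns the filtered signal.
band_filter <- function(x, fs, band) {
  ny <- fs / 2
  hi <- min(band[2] / ny, 0.99)
  bf <- if (band[1] <= 0) signal::butter(4, hi, type = "low")
        else signal::butter(4, c(band[1] / ny, hi), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

# Half peak-to-peak of a trace: the band-amplitude estimator used by the
# rejection rules.
half_p2p <- function(x) diff(range(x)) / 2

#' Flag contaminated epochs
#'
#' Tiles the recording into consecutive non-overlapping epochs of
#' `rules$epoch_len` seconds (a trailing partial epoch is dropped) and flags,
#' per channel and epoch, violations of the amplitude, fast-band and slow-band
#' rules. An epoch is kept only if every channel passes every rule.
#'
#' @param recording An `eeg_recording`.
#' @param rules A [rejection_rules()].
#' @return An object of class `epoch_mask`: list with `keep` (logical vector
#'   per epoch), `channel_keep` (channels x epochs logical matrix),
#'   `boundaries` (half-open sample intervals, 0-based) and `epoch_len`.
#' @export
reject_epochs <- function(recording, rules = rejection_rules()) {
  fs <- recording$config$fs
  len <- round(rules$epoch_len * fs)
  if (len > ncol(recording$data))
    stop("epoch_len exceeds recording duration")
  n_ep <- ncol(recording$data) %/% len
  n_ch <- nrow(recording$data)
  pad <- round(max(0, (4 - rules$epoch_len) / 2) * fs)  # slow-band extension
  ck <- matrix(TRUE, n_ch, n_ep)
  for (ch in seq_len(n_ch)) {
    x <- recording$data[ch, ]
    fast <- band_filter(x, fs, rules$fast_band)
    slow <- band_filter(x, fs, rules$slow_band)
    for (e in seq_len(n_ep)) {
      i0 <- (e - 1L) * len + 1L
      i1 <- i0 + len - 1L
      s0 <- max(1L, i0 - pad)
      s1 <- min(length(x), i1 + pad)
      ok <- max(abs(x[i0:i1])) <= rules$amp_max &&
        half_p2p(fast[i0:i1]) <= rules$fast_amp &&
        half_p2p(slow[s0:s1]) <= rules$slow_amp
      ck[ch, e] <- ok
    }
  }
  boundaries <- cbind(start = (seq_len(n_ep) - 1L) * len,
                      end = seq_len(n_ep) * len)
  structure(list(keep = apply(ck, 2, all), channel_keep = ck,
                 boundaries = boundaries, epoch_len = rules$epoch_len),
            class = "epoch_mask")
}

#' Longest run of clean epochs
#'
#' Returns the maximal run of consecutive kept epochs as a half-open sample
#' interval (0-based), ties broken by earliest start. If every epoch is
#' rejected the interval is empty (`start == end == 0`).
#'
#' @param mask An `epoch_mask` from [reject_epochs()].
#' @return List with `start`, `end` (half-open, 0-based samples) and
#'   `epochs` (1-based first/last epoch index, or `NULL` if empty).
#' @export
longest_clean_segment <- function(mask) {
  keep <- mask$keep
  if (length(keep) == 0) stop("empty mask")
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  good <- which(r$values)
  if (length(good) == 0)
    return(list(start = 0L, end = 0L, epochs = NULL))
  best <- good[which.max(r$lengths[good])]  # which.max takes earliest tie
  e0 <- starts[best]; e1 <- ends[best]
  list(start = unname(mask$boundaries[e0, "start"]),
       end = unname(mask$boundaries[e1, "end"]),
       epochs = c(e0, e1))
}

# Crop a recording to a half-open 0-based sample interval.
crop_recording <- function(recording, start, end) {
  recording$data <- recording$data[, (start + 1L):end, drop = FALSE]
  recording$config$duration <- (end - start) / recording$config$fs
  recording
}

#' Preprocess a cohort: reject, select, trim
#'
#' Applies [reject_epochs()] and [longest_clean_segment()] to every recording,
#' crops each to its clean segment, and then trims all subjects to the common
#' (minimum) clean length via [trim_to_common_length()].
#'
#' @param cohort An `eeg_cohort`.
#' @param rules A [rejection_rules()].
#' @return The preprocessed `eeg_cohort`; each recording carries its mask and
#'   chosen segment in attributes `mask` and `segment`.
#' @export
preprocess_cohort <- function(cohort, rules = rejection_rules()) {
  cohort$recordings <- lapply(cohort$recordings, function(rec) {
    mask <- reject_epochs(rec, rules)
    seg <- longest_clean_segment(mask)
    if (seg$end <= seg$start)
      stop("no clean segment for subject ", rec$subject_id)
    out <- crop_recording(rec, seg$start, seg$end)
    attr(out, "mask") <- mask
    attr(out, "segment") <- seg
    out
  })
  trim_to_common_length(cohort)
}

#' Trim all recordings to the common length
#'
#' Cuts every recording to the minimum length across subjects, taken from the
#' start of each subject's (already selected) clean segment, so that all
#' subjects contribute the same number of samples per channel. At 250 Hz a
#' common length of 43 s yields 10,750 samples per channel.
#'
#' @param cohort An `eeg_cohort` whose recordings are clean segments.
#' @return The trimmed `eeg_cohort`.
#' @export
trim_to_common_length <- function(cohort) {
  lens <- vapply(cohort$recordings, function(r) ncol(r$data), 0L)
  if (any(lens == 0)) {
    bad <- vapply(cohort$recordings[lens == 0], `[[`, "", "subject_id")
    stop("empty clean segment for subject(s): ", paste(bad, collapse = ", "))
  }
  m <- min(lens)
  cohort$recordings <- lapply(cohort$recordings, crop_recording,
                              start = 0L, end = m)
  cohort
}
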