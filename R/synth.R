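#' Recording configuration
#'
#' Describes the geometry of a multichannel EEG recording: channel count and
#' labels, sampling rate and duration. Defaults mirror a standard resting-state
#' acquisition: 19 channels in the 10/20 montage, 250 Hz.
#'
#' @param n_channels Number of channels.
#' @param channel_labels Ordered electrode labels; length must equal
#'   `n_channels`.
#' @param fs Sampling rate in Hz (> 0).
#' @param duration Recording length in seconds (> 0).
#' @return An object of class `recording_config`.
#' @export
#' @examples
#' recording_config(duration = 43)
recording_config <- function(n_channels = 19L,
                             channel_labels = montage_1020(),
                             fs = 250, duration = 60) {
  if (length(channel_labels) != n_channels)
    stop("n_channels (", n_channels, ") must equal length(channel_labels) (",
         length(channel_labels), ")")
  if (!is.numeric(fs) || fs <= 0) stop("fs must be > 0")
  if (!is.numeric(duration) || duration <= 0) stop("duration must be > 0")
  structure(list(n_channels = as.integer(n_channels),
                 channel_labels = as.character(channel_labels),
                 fs = fs, duration = duration),
            class = "recording_config")
}

#' Group effect on broadband noise share
#'
#' The generator mixes band-limited oscillations with 1/f broadband noise;
#' `noise_mix` is the broadband share of the (unit-variance) mixture in
#' `[0, 1]`. A group difference is modelled as an additive shift `delta` of the
#' noise share on `effect_channels` for the ASD group — a "noisier" signal,
#' which raises entropy and Lempel-Ziv complexity on those channels.
#'
#' @param group `"TD"` or `"ASD"`.
#' @param noise_mix Baseline broadband share in `[0, 1]`.
#' @param effect_channels Channel labels carrying the group effect.
#' @param delta Added noise share on `effect_channels` when `group == "ASD"`
#'   (result clamped to `[0, 1]`).
#' @param subject_sd Between-subject standard deviation of the noise share
#'   (one draw per subject, shared across channels).
#' @return An object of class `group_effect`.
#' @export
#' @examples
#' group_effect("ASD", delta = 0.3, effect_channels = c("O1", "Pz"))
group_effect <- function(group = c("TD", "ASD"), noise_mix = 0.4,
                         effect_channels = character(), delta = 0,
                         subject_sd = 0.05) {
  group <- match.arg(group)
  if (noise_mix < 0 || noise_mix > 1) stop("noise_mix must lie in [0, 1]")
  structure(list(group = group, noise_mix = noise_mix,
                 effect_channels = as.character(effect_channels),
                 delta = delta, subject_sd = subject_sd),
            class = "group_effect")
}

# 1/f-shaped Gaussian noise of length n, unit sd: spectral shaping of white
# noise with amplitude ~ f^(-exponent/2 * 2) i.e. power ~ 1/f^exponent.
pink_noise <- function(n, fs, exponent = 1) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  f[f > fs / 2] <- fs - f[f > fs / 2]   # mirror negative frequencies
  scale <- ifelse(f > 0, f^(-exponent / 2), 0)
  x <- Re(stats::fft(W * scale, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Band-limited oscillatory component, unit sd: two random-frequency,
# random-phase sinusoids per canonical band, weighted for resting EEG, under
# a shared slow amplitude envelope. The envelope emulates the waxing and
# waning of rhythmic activity and gives the oscillatory amplitudes a
# leptokurtic (burst-like) distribution, so that adding broadband noise
# raises the amplitude-distribution entropies.
oscillatory_component <- function(n, fs) {
  bands <- list(delta = c(1, 4), theta = c(4, 8),
                alpha = c(8, 13), beta = c(13, 30))
  weights <- c(delta = 1, theta = 0.8, alpha = 1, beta = 0.4)
  t <- seq_len(n) / fs
  x <- numeric(n)
  for (b in names(bands)) {
    for (k in 1:2) {
      f0 <- stats::runif(1, bands[[b]][1], bands[[b]][2])
      ph <- stats::runif(1, 0, 2 * pi)
      x <- x + weights[[b]] * sin(2 * pi * f0 * t + ph)
    }
  }
  fm <- stats::runif(1, 0.1, 0.4)
  phm <- stats::runif(1, 0, 2 * pi)
  x <- x * (1 + sin(2 * pi * fm * t + phm)) / 2
  x / stats::sd(x)
}

#' Generate one synthetic EEG recording
#'
#' Each channel is a weighted sum of band-limited oscillations (delta 1-4,
#' theta 4-8, alpha 8-13, beta 13-30 Hz sinusoids with random frequency and
#' phase, shared across channels) and channel-independent 1/f broadband noise.
#' The broadband share is set by the effect's `noise_mix` (plus `delta` on
#' `effect_channels` for the ASD group, plus one per-subject jitter draw).
#' Channels are scaled to a physiologic amplitude (10 uV RMS, peaks within
#' roughly +/- 50 uV). Deterministic given `seed`.
#'
#' @param config A [recording_config()].
#' @param effect A [group_effect()].
#' @param seed Integer seed governing all randomness for this recording.
#' @param subject_id Identifier attached to the recording.
#' @param amp_sd Per-channel RMS amplitude in uV.
#' @return An object of class `eeg_recording`: a list with `data`
#'   (channels x samples matrix, uV, rownames = channel labels), `config`,
#'   `subject_id` and `group`.
#' @export
#' @examples
#' rec <- generate_recording(recording_config(duration = 2),
#'                           group_effect("TD"), seed = 1)
#' dim(rec$data)
generate_recording <- function(config, effect, seed, subject_id = "S1",
                               amp_sd = 10) {
  stopifnot(inherits(config, "recording_config"),
            inherits(effect, "group_effect"))
  set.seed(as.integer(seed %% 2147483647L))
  n <- round(config$fs * config$duration)
  osc <- oscillatory_component(n, config$fs)
  jitter <- stats::rnorm(1, 0, effect$subject_sd)
  data <- matrix(0, nrow = config$n_channels, ncol = n,
                 dimnames = list(config$channel_labels, NULL))
  for (ch in seq_len(config$n_channels)) {
    mix <- effect$noise_mix + jitter +
      if (effect$group == "ASD" &&
          config$channel_labels[ch] %in% effect$effect_channels)
        effect$delta else 0
    mix <- min(max(mix, 0), 1)
    x <- (1 - mix) * osc + mix * pink_noise(n, config$fs)
    data[ch, ] <- amp_sd * x / stats::sd(x)
  }
  structure(list(data = data, config = config, subject_id = subject_id,
                 group = effect$group),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s (%s): %d channels x %d samples @ %g Hz\n",
              x$subject_id, x$group, nrow(x$data), ncol(x$data), x$config$fs))
  invisible(x)
}

#' Inject a stereotyped artifact into one epoch
#'
#' Adds, to a single epoch of a single channel, one of the three artifact
#' classes that the rejection rules screen for: `spike` (a transient exceeding
#' 100 uV), `fast` (a 25 Hz component exceeding 35 uV), or `slow` (a 0.75 Hz
#' component with a 90 uV swing, exceeding the 50 uV slow-band criterion; like
#' real movement artifacts it usually also crosses the raw-amplitude rule).
#' Samples outside the designated epoch are left untouched.
#'
#' @param recording An `eeg_recording`.
#' @param kind `"spike"`, `"fast"` or `"slow"`.
#' @param epoch_index 1-based index of the epoch to contaminate.
#' @param epoch_len Epoch length in seconds.
#' @param channel Channel index receiving the artifact.
#' @return The modified `eeg_recording`.
#' @export
inject_artifacts <- function(recording, kind = c("spike", "fast", "slow"),
                             epoch_index, epoch_len = 1, channel = 1L) {
  kind <- match.arg(kind)
  fs <- recording$config$fs
  n <- ncol(recording$data)
  len <- round(epoch_len * fs)
  start <- (epoch_index - 1L) * len + 1L
  if (epoch_index < 1 || start + len - 1L > n)
    stop("epoch_index ", epoch_index, " outside recording")
  idx <- start:(start + len - 1L)
  t <- (seq_along(idx) - 1) / fs
  add <- switch(kind,
    spike = 200 * exp(-((t - epoch_len / 2)^2) / (2 * 0.01^2)),
    fast  = 45 * sin(2 * pi * 25 * t),
    slow  = 90 * sin(2 * pi * 0.75 * t))
  recording$data[channel, idx] <- recording$data[channel, idx] + add
  recording
}

#' Generate a synthetic two-group EEG cohort
#'
#' Generates `n_td + n_asd` recordings with per-subject seeds derived from the
#' single cohort seed by a counter scheme, so cohorts of any size are
#' reproducible and no two subjects are identical.
#'
#' @param n_td,n_asd Group sizes (>= 1). The study design this emulates has
#'   39 TD and 49 ASD children.
#' @param config A [recording_config()] shared by all subjects.
#' @param effect A [group_effect()]; its `group` field is overridden per
#'   subject.
#' @param seed Integer cohort seed.
#' @return An object of class `eeg_cohort`: list of recordings plus the seed.
#' @export
#' @examples
#' coh <- generate_cohort(3, 3, recording_config(duration = 2),
#'                        group_effect(), seed = 1)
#' length(coh$recordings)
generate_cohort <- function(n_td, n_asd, config, effect, seed) {
  if (n_td < 1 || n_asd < 1) stop("group sizes must be >= 1")
  groups <- c(rep("TD", n_td), rep("ASD", n_asd))
  ids <- c(sprintf("TD%02d", seq_len(n_td)), sprintf("ASD%02d", seq_len(n_asd)))
  recs <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    eff_i <- effect
    eff_i$group <- groups[i]
    sub_seed <- (as.numeric(seed) + 7919 * i) %% 2147483647
    recs[[i]] <- generate_recording(config, eff_i, seed = sub_seed,
                                    subject_id = ids[i])
  }
  structure(list(recordings = recs, seed = seed), class = "eeg_cohort")
}

#' @export
print.eeg_cohort <- function(x, ...) {
  grp <- vapply(x$recordings, `[[`, "", "group")
  cat(sprintf("<eeg_cohort> %d recordings (TD %d / ASD %d), seed %s\n",
              length(grp), sum(grp == "TD"), sum(grp == "ASD"),
              format(x$seed)))
  invisible(x)
}
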