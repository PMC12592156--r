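# EEG conditioning chain: broadband zero-phase filtering, polyphase
# downsampling, epoching around stimulus onsets, amplitude-based trial
# rejection, distance-weighted channel interpolation, and the final
# 1-15 Hz band limit. The fixed order is: band-limit -> 256 Hz -> epoch
# -> reject/interpolate -> 1-15 Hz band-pass -> 128 Hz.

apply_filtfilt <- function(data, flt) {
  apply(as.matrix(data), 2, function(col) signal::filtfilt(flt, col))
}

#' Broadband zero-phase filtering of a raw recording
#'
#' Applies a zero-phase 1-Hz high-pass (narrow 0.5-Hz transition) and a
#' zero-phase 57-Hz low-pass (wider 2-Hz transition) to every channel.
#' Both are Butterworth designs run forward-backward, so filtered
#' symmetric pulses keep their peak sample (zero group delay).
#'
#' @param rec A [raw_recording()] with `fs >= 512` Hz.
#' @param hp_hz,lp_hz Filter edges in Hz.
#' @return The filtered [raw_recording()].
#' @export
bandlimit_raw <- function(rec, hp_hz = 1, lp_hz = 57) {
  stopifnot(inherits(rec, "raw_recording"))
  if (rec$fs < 512) abort("bandlimit_raw expects a sampling rate of at least 512 Hz")
  if (rec$fs < 2 * lp_hz) abort("sampling rate below twice the low-pass edge")
  hp <- signal::butter(2, hp_hz / (rec$fs / 2), type = "high")
  lp <- signal::butter(4, lp_hz / (rec$fs / 2), type = "low")
  rec$data <- apply_filtfilt(apply_filtfilt(rec$data, hp), lp)
  rec
}

#' Resample a recording or trial set
#'
#' Polyphase rational-ratio resampling with a zero-phase anti-alias FIR.
#' Event sample indices of a raw recording are rescaled with the data.
#'
#' @param x A [raw_recording()] or [trial_set()].
#' @param target_fs Target rate in Hz; the ratio to the current rate
#'   must be rational with a small denominator (irrational ratios error).
#' @return The same type of object at `target_fs`.
#' @export
resample_eeg <- function(x, target_fs) {
  UseMethod("resample_eeg")
}

#' @export
resample_eeg.raw_recording <- function(x, target_fs) {
  if (target_fs >= x$fs) abort("target_fs must be below the current rate")
  r <- rational_ratio(target_fs, x$fs)
  x$data <- apply(x$data, 2, resample_series, p = r["p"], q = r["q"])
  x$events$sample <- pmax(1L, round((x$events$sample - 1) * target_fs / x$fs) + 1L)
  x$fs <- target_fs
  x
}

#' @export
resample_eeg.trial_set <- function(x, target_fs) {
  if (target_fs >= x$fs) abort("target_fs must be below the current rate")
  r <- rational_ratio(target_fs, x$fs)
  d <- dim(x$data)
  n_new <- as.integer(ceiling(d[3] * unname(r["p"] / r["q"])))
  out <- array(0, dim = c(d[1], d[2], n_new))
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      out[i, j, ] <- resample_series(x$data[i, j, ], r["p"], r["q"])
    }
  }
  x$data <- out
  x$fs <- target_fs
  x
}

#' Epoch a recording around its stimulus onsets
#'
#' Cuts one epoch per event, from `pre_s` before to `post_s` after the
#' onset sample, grouped by sentence. Events too close to a recording
#' edge are dropped and logged rather than producing short epochs.
#'
#' @param rec A [raw_recording()].
#' @param pre_s,post_s Epoch extent in seconds (defaults 0.5 and 2.5).
#' @return Named list of [trial_set()]s, one per sentence.
#' @export
epoch_recording <- function(rec, pre_s = 0.5, post_s = 2.5) {
  stopifnot(inherits(rec, "raw_recording"))
  n_pre <- round(pre_s * rec$fs)
  n_post <- round(post_s * rec$fs)
  n_samp <- n_pre + n_post
  out <- list()
  for (sent in unique(rec$events$sentence)) {
    ev <- rec$events$sample[rec$events$sentence == sent]
    ok <- ev - n_pre >= 1 & ev + n_post - 1 <= nrow(rec$data)
    kept <- ev[ok]
    dat <- array(0, dim = c(length(kept), ncol(rec$data), n_samp))
    for (i in seq_along(kept)) {
      dat[i, , ] <- t(rec$data[(kept[i] - n_pre):(kept[i] + n_post - 1), ])
    }
    out[[as.character(sent)]] <- trial_set(
      dat, rec$fs, pre_s = pre_s, sentence = as.character(sent),
      channels = rec$channels, positions = rec$positions,
      log = list(dropped = which(!ok), interpolated = character())
    )
  }
  out
}

#' Amplitude-based trial rejection
#'
#' Drops every trial in which any channel exceeds the threshold in
#' absolute value (strictly; a sample exactly at the threshold is kept),
#' recording the dropped trial indices in the rejection log.
#'
#' @param trials A [trial_set()] in microvolts (not yet z-scored).
#' @param threshold_uv Rejection threshold in microvolts (default 200).
#' @return The pruned [trial_set()].
#' @export
reject_amplitude <- function(trials, threshold_uv = 200) {
  stopifnot(inherits(trials, "trial_set"))
  if (identical(trials$units, "z")) {
    abort("amplitude rejection must run before z-normalization")
  }
  peak <- apply(abs(trials$data), 1, max)
  bad <- which(peak > threshold_uv)
  if (length(bad) == n_trials(trials)) {
    abort(sprintf("all trials of sentence %s exceed %g uV", trials$sentence, threshold_uv))
  }
  if (length(bad)) {
    trials$log$dropped <- c(trials$log$dropped, bad)
    trials$data <- trials$data[-bad, , , drop = FALSE]
  }
  trials
}

#' Interpolate bad channels from their neighbors
#'
#' Replaces each listed channel by an inverse-distance-weighted average
#' of the good channels (2-D sensor layout). Good channels are left
#' untouched; repaired channels are recorded in the log.
#'
#' @param trials A [trial_set()] with sensor positions.
#' @param bad Character vector of channel labels (or integer indices).
#' @param power Inverse-distance exponent (default 2).
#' @return The repaired [trial_set()].
#' @export
interpolate_channels <- function(trials, bad, power = 2) {
  stopifnot(inherits(trials, "trial_set"))
  if (!length(bad)) return(trials)
  idx <- if (is.character(bad)) match(bad, trials$channels) else as.integer(bad)
  if (any(is.na(idx)) || any(idx < 1 | idx > length(trials$channels))) {
    abort("bad channel not found")
  }
  n_ch <- length(trials$channels)
  if (length(idx) > 0.25 * n_ch) {
    abort(sprintf("%d of %d channels marked bad; interpolation unreliable above 25%%",
                  length(idx), n_ch))
  }
  if (is.null(trials$positions)) abort("sensor positions are required for interpolation")
  good <- setdiff(seq_len(n_ch), idx)
  if (length(good) < 3) abort("fewer than 3 good channels available")
  for (b in idx) {
    d <- sqrt(rowSums((trials$positions[good, , drop = FALSE] -
                         matrix(trials$positions[b, ], length(good), 2, byrow = TRUE))^2))
    w <- 1 / pmax(d, 1e-6)^power
    w <- w / sum(w)
    est <- apply(trials$data[, good, , drop = FALSE], c(1, 3),
                 function(v) sum(v * w))
    trials$data[, b, ] <- est
  }
  trials$log$interpolated <- c(trials$log$interpolated, trials$channels[idx])
  trials
}

#' Final 1-15 Hz band limit
#'
#' Order-5 zero-phase Butterworth band-pass over the band carrying
#' low-frequency neural tracking of speech.
#'
#' @param trials A [trial_set()] with `fs >= 64` Hz.
#' @param band_hz Band edges in Hz (default `c(1, 15)`).
#' @return The filtered [trial_set()].
#' @export
final_bandpass <- function(trials, band_hz = c(1, 15)) {
  stopifnot(inherits(trials, "trial_set"))
  if (trials$fs < 64) abort("final_bandpass expects a sampling rate of at least 64 Hz")
  bp <- signal::butter(5, band_hz / (trials$fs / 2), type = "pass")
  d <- dim(trials$data)
  for (i in seq_len(d[1])) {
    trials$data[i, , ] <- t(apply_filtfilt(t(trials$data[i, , , drop = TRUE]), bp))
  }
  trials
}

#' Full preprocessing chain
#'
#' Runs the fixed conditioning order on a raw recording: broadband
#' band-limit, downsample to `mid_fs` (256 Hz), epoch, amplitude
#' rejection, optional channel interpolation, 1-15 Hz band-pass, and
#' downsample to `final_fs` (128 Hz). Each trial set's log accounts for
#' all dropped trials and repaired channels.
#'
#' @param rec A [raw_recording()].
#' @param bad_channels Channel labels to interpolate (explicitly
#'   supplied; see [detect_bad_channels()] for an optional detector).
#' @param threshold_uv Amplitude rejection threshold.
#' @param mid_fs,final_fs Intermediate and final sampling rates.
#' @param pre_s,post_s Epoch extent in seconds.
#' @return Named list of [trial_set()]s at `final_fs`.
#' @export
preprocess_raw <- function(rec, bad_channels = character(), threshold_uv = 200,
                           mid_fs = 256, final_fs = 128,
                           pre_s = 0.5, post_s = 2.5) {
  rec <- bandlimit_raw(rec)
  rec <- resample_eeg(rec, mid_fs)
  trials <- epoch_recording(rec, pre_s = pre_s, post_s = post_s)
  trials <- lapply(trials, function(ts) {
    ts <- reject_amplitude(ts, threshold_uv = threshold_uv)
    ts <- interpolate_channels(ts, bad_channels)
    ts <- final_bandpass(ts)
    resample_eeg(ts, final_fs)
  })
  trials
}

#' Artifact-removal hook
#'
#' Placeholder stage for component-based artifact removal (e.g. ocular
#' ICA). No selection criterion is built in, so the default method
#' `"none"` passes the data through unchanged and records the skip in
#' the rejection log; synthetic cohorts contain no ocular artifacts.
#'
#' @param trials A [trial_set()].
#' @param method Only `"none"` is implemented.
#' @return The unchanged [trial_set()] with the skip logged.
#' @export
remove_artifacts <- function(trials, method = "none") {
  stopifnot(inherits(trials, "trial_set"))
  if (!identical(method, "none")) {
    abort("only method = \"none\" (pass-through) is implemented")
  }
  trials$log$artifact_removal <- "skipped (no component-selection criterion configured)"
  trials
}

#' Optional robust bad-channel detector
#'
#' Flags channels whose log-variance (over all trials and samples) is a
#' robust-z outlier. Off by default in the pipeline; bad channels are
#' normally supplied explicitly.
#'
#' @param trials A [trial_set()] or list of them.
#' @param z_cut Robust z-score threshold (default 3.5).
#' @return Character vector of flagged channel labels.
#' @export
detect_bad_channels <- function(trials, z_cut = 3.5) {
  if (inherits(trials, "trial_set")) trials <- list(trials)
  v <- Reduce(`+`, lapply(trials, function(ts) apply(ts$data, 2, var)))
  lv <- log(v)
  z <- (lv - stats::median(lv)) / (stats::mad(lv) + 1e-12)
  trials[[1]]$channels[abs(z) > z_cut]
}
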