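#' Epoched EEG trials for one sentence
#'
#' A `trial_set` holds the epoched EEG for one stimulus sentence as a
#' `trial x channel x sample` array together with its sampling rate and a
#' time axis whose zero is the stimulus onset. A rejection log accounts
#' for every trial dropped and every channel interpolated along the way,
#' so `kept + dropped` always equals the number of trials that entered.
#'
#' @param data Numeric array `trial x channel x sample` (microvolts, or
#'   z-units after normalization).
#' @param fs Sampling rate in Hz.
#' @param pre_s Seconds of data before stimulus onset (default 0.5).
#' @param sentence Sentence identifier.
#' @param channels Optional character vector of channel labels.
#' @param positions Optional `channel x 2` matrix of 2-D sensor positions
#'   (used by channel interpolation).
#' @param log List with elements `dropped` (indices of removed trials,
#'   in the numbering of the original trial sequence) and `interpolated`
#'   (labels of repaired channels).
#' @param units `"uV"` or `"z"`.
#'
#' @return An object of class `trial_set`.
#' @export
trial_set <- function(data, fs, pre_s = 0.5, sentence = NA_character_,
                      channels = NULL, positions = NULL,
                      log = list(dropped = integer(), interpolated = character()),
                      units = "uV") {
  data <- as.array(data)
  if (length(dim(data)) != 3) abort("trial data must be a trial x channel x sample array")
  if (!is.finite(fs) || fs <= 0) abort("fs must be positive")
  n_ch <- dim(data)[2]
  channels <- channels %||% sprintf("ch%02d", seq_len(n_ch))
  if (length(channels) != n_ch) abort("channel labels do not match data")
  if (!is.null(positions)) {
    positions <- as.matrix(positions)
    if (nrow(positions) != n_ch) abort("positions must have one row per channel")
  }
  structure(
    list(data = data, fs = fs, pre_s = pre_s, sentence = sentence,
         channels = channels, positions = positions, log = log, units = units),
    class = "trial_set"
  )
}

#' @export
print.trial_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<trial_set> sentence %s: %d trials x %d channels x %d samples @ %g Hz (%s)\n",
              x$sentence, d[1], d[2], d[3], x$fs, x$units))
  cat(sprintf("  time %.0f..%.0f ms; dropped %d trial(s); interpolated: %s\n",
              min(ts_time(x)) * 1000, max(ts_time(x)) * 1000,
              length(x$log$dropped),
              if (length(x$log$interpolated)) paste(x$log$interpolated, collapse = ",") else "none"))
  invisible(x)
}

# Time axis in seconds, zero at stimulus onset.
ts_time <- function(x) {
  n <- dim(x$data)[3]
  (seq_len(n) - 1 - round(x$pre_s * x$fs)) / x$fs
}

n_trials <- function(x) dim(x$data)[1]

# Index of the onset sample (time zero) within the sample axis.
onset_index <- function(x) round(x$pre_s * x$fs) + 1L

# Matrix (sample x channel) for one trial, optionally post-onset only.
trial_matrix <- function(x, i, post_only = FALSE) {
  m <- t(x$data[i, , , drop = TRUE])
  if (is.null(dim(m))) m <- matrix(m, ncol = dim(x$data)[2])
  if (post_only) m <- m[onset_index(x):nrow(m), , drop = FALSE]
  m
}

#' @export
tidy.trial_set <- function(x, ...) {
  d <- dim(x$data)
  tibble(
    trial = rep(seq_len(d[1]), times = d[2] * d[3]),
    channel = rep(rep(x$channels, each = d[1]), times = d[3]),
    time_s = rep(ts_time(x), each = d[1] * d[2]),
    value = as.vector(x$data)
  )
}

#' Stimulus feature series aligned to the EEG analysis grid
#'
#' A `feature_series` is one stimulus representation sampled at the EEG
#' analysis rate, with time zero at stimulus onset: the dense speech
#' envelope, or a sparse impulse train (phoneme onsets, surprisal-scaled
#' onsets, dissimilarity-scaled word onsets).
#'
#' @param values Numeric vector of feature samples starting at onset.
#' @param fs Sampling rate in Hz.
#' @param name Feature name, one of `"Env"`, `"Pon"`, `"Ps"`, `"Sem"` or a
#'   custom label (the synthetic generator also uses manner-category names).
#' @param sentence Sentence identifier.
#' @return An object of class `feature_series`.
#' @export
feature_series <- function(values, fs, name, sentence = NA_character_) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) abort("feature values must be finite")
  structure(list(name = name, values = values, fs = fs, sentence = sentence),
            class = "feature_series")
}

#' @export
print.feature_series <- function(x, ...) {
  cat(sprintf("<feature_series> %s, sentence %s: %d samples @ %g Hz\n",
              x$name, x$sentence, length(x$values), x$fs))
  invisible(x)
}

#' @export
tidy.feature_series <- function(x, ...) {
  tibble(name = x$name, sentence = x$sentence,
         time_s = (seq_along(x$values) - 1) / x$fs, value = x$values)
}

#' Raw continuous EEG recording
#'
#' A continuous multi-channel recording with stimulus-onset events, the
#' input to the preprocessing chain.
#'
#' @param data Numeric `sample x channel` matrix in microvolts.
#' @param fs Sampling rate in Hz.
#' @param events Tibble with columns `sentence` and `sample` (1-based
#'   onset sample index).
#' @param channels Optional channel labels.
#' @param positions Optional `channel x 2` position matrix.
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(data, fs, events, channels = NULL, positions = NULL) {
  data <- as.matrix(data)
  if (!is.finite(fs) || fs <= 0) abort("fs must be positive")
  events <- as_tibble(events)
  if (!all(c("sentence", "sample") %in% names(events))) {
    abort("events must have columns `sentence` and `sample`")
  }
  if (any(events$sample < 1 | events$sample > nrow(data))) {
    abort("event samples fall outside the recording")
  }
  channels <- channels %||% sprintf("ch%02d", seq_len(ncol(data)))
  structure(list(data = data, fs = fs, events = events,
                 channels = channels, positions = positions),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d samples x %d channels @ %g Hz, %d events\n",
              nrow(x$data), ncol(x$data), x$fs, nrow(x$events)))
  invisible(x)
}
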