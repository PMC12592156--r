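# Phoneme-related potentials: whole-recording channel z-normalization,
# epoching of -50..500 ms windows around every phoneme onset, and
# averaging per phoneme, per manner-of-articulation category and overall.

#' Z-normalize channels over a subject's whole recording
#'
#' Normalizes each channel to zero mean and unit variance over the
#' concatenation of all trials of all supplied trial sets (one subject),
#' the normalization applied before phoneme-related potentials are
#' extracted.
#'
#' @param trials A [trial_set()] or named list of them (one subject).
#' @return The same structure with `units = "z"`.
#' @export
znorm_channels <- function(trials) {
  single <- inherits(trials, "trial_set")
  tl <- if (single) list(trials) else trials
  n_ch <- dim(tl[[1]]$data)[2]
  sums <- numeric(n_ch)
  sq <- numeric(n_ch)
  count <- 0
  for (ts in tl) {
    sums <- sums + apply(ts$data, 2, sum)
    sq <- sq + apply(ts$data^2, 2, sum)
    count <- count + dim(ts$data)[1] * dim(ts$data)[3]
  }
  mu <- sums / count
  v <- sq / count - mu^2
  if (any(v <= 0)) {
    abort(sprintf("channel %s has zero variance; cannot z-normalize",
                  tl[[1]]$channels[which(v <= 0)[1]]))
  }
  s <- sqrt(v)
  out <- lapply(tl, function(ts) {
    for (j in seq_len(n_ch)) ts$data[, j, ] <- (ts$data[, j, ] - mu[j]) / s[j]
    ts$units <- "z"
    ts
  })
  if (single) out[[1]] else out
}

#' Epoch z-scored trials around phoneme onsets
#'
#' Cuts a `-50..500` ms window around every phoneme onset of every
#' retained trial and stacks the epochs per phoneme. Onsets whose window
#' does not fit inside the trial are dropped and logged. The epoch count
#' of a phoneme equals its occurrence count times the number of retained
#' trials.
#'
#' @param trials A [trial_set()] or named list of them.
#' @param annotations A phoneme annotation tibble (columns `phoneme`,
#'   `manner`, `onset_s`), or a named list matching `trials`.
#' @param window_ms Epoch window around each onset (default `c(-50, 500)`).
#' @return An object of class `prp_epochs`: per-phoneme arrays
#'   (`epoch x channel x sample`), the time axis, manner lookup and a
#'   drop log.
#' @export
epoch_phonemes <- function(trials, annotations, window_ms = c(-50, 500)) {
  if (inherits(trials, "trial_set")) trials <- list(trials)
  if (is.data.frame(annotations)) annotations <- list(annotations)
  if (length(trials) != length(annotations)) {
    abort("need one annotation per trial set")
  }
  if (!is.null(names(trials)) && !is.null(names(annotations))) {
    annotations <- annotations[names(trials)]
  }
  fs <- trials[[1]]$fs
  w0 <- round(window_ms[1] * fs / 1000)
  w1 <- round(window_ms[2] * fs / 1000)
  n_win <- w1 - w0 + 1L
  stacks <- list()
  manner_of <- character()
  dropped <- 0L
  for (s in seq_along(trials)) {
    ts <- trials[[s]]
    ann <- annotations[[s]]
    n_samp <- dim(ts$data)[3]
    on0 <- onset_index(ts)
    for (r in seq_len(nrow(ann))) {
      centre <- on0 + time_to_sample(ann$onset_s[r], fs)
      lo <- centre + w0
      hi <- centre + w1
      if (lo < 1 || hi > n_samp) {
        dropped <- dropped + n_trials(ts)
        next
      }
      ph <- ann$phoneme[r]
      manner_of[ph] <- ann$manner[r]
      seg <- ts$data[, , lo:hi, drop = FALSE]
      stacks[[ph]] <- if (is.null(stacks[[ph]])) seg else {
        abind_first(stacks[[ph]], seg)
      }
    }
  }
  structure(list(
    stacks = stacks,
    manner = manner_of,
    time_ms = seq(w0, w1) / fs * 1000,
    fs = fs,
    channels = trials[[1]]$channels,
    dropped_epochs = dropped
  ), class = "prp_epochs")
}

# Bind two epoch x channel x sample arrays along the first dimension.
abind_first <- function(a, b) {
  da <- dim(a)
  db <- dim(b)
  out <- array(0, dim = c(da[1] + db[1], da[2], da[3]))
  out[seq_len(da[1]), , ] <- a
  out[da[1] + seq_len(db[1]), , ] <- b
  out
}

#' Average phoneme epochs into phoneme-related potentials
#'
#' Computes the mean response per phoneme (`channel x time`), per manner
#' category (mean over all epochs of its member phonemes, i.e.
#' epoch-weighted) and the grand average over all epochs and electrodes
#' (a single time course). An optional pre-onset baseline correction is
#' available but off by default. Phonemes with zero epochs are excluded
#' and listed.
#'
#' @param epochs A [epoch_phonemes()] result.
#' @param weighting `"epoch"` (default) or `"phoneme"`: whether category
#'   and grand averages weight every epoch equally or every phoneme
#'   equally.
#' @param baseline_correct Subtract each epoch's mean over the pre-onset
#'   part of the window (default `FALSE`).
#' @return An object of class `prp_set` with per-phoneme and per-category
#'   mean responses, epoch counts, and the grand-average trace.
#' @export
average_prp <- function(epochs, weighting = c("epoch", "phoneme"),
                        baseline_correct = FALSE) {
  stopifnot(inherits(epochs, "prp_epochs"))
  weighting <- match.arg(weighting)
  stacks <- epochs$stacks
  counts <- vapply(stacks, function(a) dim(a)[1], integer(1))
  empty <- names(counts)[counts == 0]
  stacks <- stacks[counts > 0]
  counts <- counts[counts > 0]
  if (!length(stacks)) abort("no phoneme epochs to average")
  if (baseline_correct) {
    pre <- which(epochs$time_ms < 0)
    stacks <- lapply(stacks, function(a) {
      base <- apply(a[, , pre, drop = FALSE], c(1, 2), mean)
      sweep(a, c(1, 2), base)
    })
  }
  phoneme_mean <- lapply(stacks, function(a) apply(a, c(2, 3), mean))

  categories <- manner_levels()[manner_levels() %in% epochs$manner[names(stacks)]]
  category_mean <- list()
  category_counts <- integer()
  for (mn in categories) {
    members <- names(stacks)[epochs$manner[names(stacks)] == mn]
    if (weighting == "epoch") {
      tot <- Reduce(`+`, lapply(members, function(ph) phoneme_mean[[ph]] * counts[ph]))
      category_mean[[mn]] <- tot / sum(counts[members])
    } else {
      category_mean[[mn]] <- Reduce(`+`, phoneme_mean[members]) / length(members)
    }
    category_counts[mn] <- sum(counts[members])
  }
  if (weighting == "epoch") {
    tot <- Reduce(`+`, lapply(names(stacks), function(ph) phoneme_mean[[ph]] * counts[ph]))
    grand_map <- tot / sum(counts)
  } else {
    grand_map <- Reduce(`+`, phoneme_mean) / length(phoneme_mean)
  }
  grand <- colMeans(grand_map)

  structure(list(
    phoneme = phoneme_mean,
    counts = counts,
    category = category_mean,
    category_counts = category_counts,
    grand = grand,
    manner = epochs$manner[names(stacks)],
    time_ms = epochs$time_ms,
    fs = epochs$fs,
    channels = epochs$channels,
    weighting = weighting,
    excluded = empty
  ), class = "prp_set")
}

#' Similarity between two grand-average PRP traces
#'
#' Pearson correlation over the `-50..500` ms grand-average traces of two
#' groups, a scalar summary of how alike their phoneme-locked responses
#' are.
#'
#' @param a,b `prp_set` objects or numeric grand-average traces.
#' @return Pearson r.
#' @export
prp_similarity <- function(a, b) {
  ta <- if (inherits(a, "prp_set")) a$grand else as.numeric(a)
  tb <- if (inherits(b, "prp_set")) b$grand else as.numeric(b)
  if (length(ta) != length(tb)) abort("grand-average traces differ in length")
  safe_cor(ta, tb)
}

#' @export
print.prp_set <- function(x, ...) {
  cat(sprintf("<prp_set> %d phonemes, %d categories, %d epochs total\n",
              length(x$phoneme), length(x$category), sum(x$counts)))
  cat(sprintf("  window %.0f..%.0f ms @ %g Hz; weighting: %s\n",
              min(x$time_ms), max(x$time_ms), x$fs, x$weighting))
  if (length(x$excluded)) {
    cat("  excluded (no epochs):", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.prp_set <- function(x, ...) {
  rows <- lapply(names(x$phoneme), function(ph) {
    tibble(phoneme = ph, manner = unname(x$manner[ph]),
           time_ms = x$time_ms,
           value = colMeans(x$phoneme[[ph]]),
           n_epochs = unname(x$counts[ph]))
  })
  bind_rows(rows)
}

#' @export
glance.prp_set <- function(x, ...) {
  tibble(n_phonemes = length(x$phoneme),
         n_categories = length(x$category),
         n_epochs = sum(x$counts),
         weighting = x$weighting)
}

#' @export
autoplot.prp_set <- function(object, ...) {
  df <- bind_rows(lapply(names(object$category), function(mn) {
    tibble(category = mn, time_ms = object$time_ms,
           value = colMeans(object$category[[mn]]))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms, y = .data$value,
                                   colour = .data$category)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(x = "time from phoneme onset (ms)", y = "PRP (z-units)",
                  colour = "manner") +
    ggplot2::theme_minimal()
}
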