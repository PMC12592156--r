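# The four stimulus representations used for neural-tracking analysis,
# all delivered at the EEG analysis rate (128 Hz by default): the dense
# Hilbert envelope and three sparse impulse trains (phoneme onsets,
# surprisal-scaled phoneme onsets, dissimilarity-scaled word onsets).

#' Speech envelope via the Hilbert transform
#'
#' Computes the slow amplitude modulation of a speech waveform as the
#' magnitude of the analytic signal, low-passed at 15 Hz with a
#' zero-phase order-5 Butterworth filter and resampled to the EEG
#' analysis rate. Tiny filter undershoot is clipped at zero so the
#' envelope stays nonnegative.
#'
#' @param audio Numeric waveform.
#' @param fs Audio sampling rate in Hz (at least 8 kHz).
#' @param target_fs Output rate in Hz (default 128).
#' @param sentence Sentence identifier carried into the result.
#' @return A [feature_series()] named `"Env"`.
#' @export
envelope <- function(audio, fs, target_fs = 128, sentence = NA_character_) {
  if (fs < 8000) abort("audio sampling rate must be at least 8 kHz")
  if (any(!is.finite(audio))) abort("audio must be finite")
  env <- Mod(analytic_signal(audio))
  # Decimate to an intermediate rate before the 15-Hz filter so the
  # normalized cutoff stays in a numerically comfortable range; both
  # stages are zero-phase so envelope timing is unaffected.
  mid_fs <- 512
  r <- rational_ratio(mid_fs, fs)
  env_mid <- resample_series(env, r["p"], r["q"])
  bf <- signal::butter(5, 15 / (mid_fs / 2), type = "low")
  env_f <- signal::filtfilt(bf, env_mid)
  r2 <- rational_ratio(target_fs, mid_fs)
  out <- resample_series(env_f, r2["p"], r2["q"])
  feature_series(pmax(out, 0), target_fs, "Env", sentence = sentence)
}

#' Phoneme-onset impulse train
#'
#' Places a unit impulse at the nearest analysis sample (half-up
#' rounding) of every phoneme onset.
#'
#' @param annotation Tibble with at least an `onset_s` column, or a
#'   numeric vector of onsets in seconds.
#' @param duration_s Series duration in seconds; the series has
#'   `ceiling(duration_s * fs)` samples.
#' @param fs Analysis rate in Hz (default 128).
#' @param sentence Sentence identifier.
#' @return A [feature_series()] named `"Pon"`.
#' @export
phoneme_onsets <- function(annotation, duration_s, fs = 128,
                           sentence = NA_character_) {
  onsets <- if (is.data.frame(annotation)) annotation$onset_s else as.numeric(annotation)
  n <- ceiling(duration_s * fs)
  if (any(onsets < 0 | onsets >= duration_s)) {
    abort(sprintf("onset outside [0, %g) s", duration_s))
  }
  v <- numeric(n)
  if (length(onsets)) {
    idx <- time_to_sample(onsets, fs) + 1L
    if (anyDuplicated(idx)) {
      abort("two phoneme onsets map to the same sample; onsets violate the spacing floor")
    }
    v[idx] <- 1
  }
  feature_series(v, fs, "Pon", sentence = sentence)
}

# Summed frequency of lexicon words whose pronunciation starts with the
# given phoneme prefix; the empty prefix returns the total frequency.
prefix_frequency <- function(lexicon, prefix) {
  if (!length(prefix)) return(sum(lexicon$frequency))
  prons <- strsplit(lexicon$pronunciation, " ", fixed = TRUE)
  hit <- vapply(prons, function(p) {
    length(p) >= length(prefix) && all(p[seq_along(prefix)] == prefix)
  }, logical(1))
  sum(lexicon$frequency[hit])
}

#' Phonemic surprisal of a word's phoneme sequence
#'
#' Surprisal of each phoneme given the word's preceding phonemes, in
#' bits: `s_k = -log2( F(p_1..k) / F(p_1..k-1) )` where `F(prefix)` is
#' the summed corpus frequency of lexicon words whose pronunciation
#' begins with that prefix (the cohort model of lexical access). The
#' per-word surprisals sum to `-log2` of the word's lexicon probability.
#'
#' @param lexicon A lexicon tibble (see [read_lexicon()]).
#' @param pronunciation Character vector of phoneme labels, or a single
#'   space-separated string.
#' @param smoothing `"none"` (default; an unseen prefix continuation is
#'   an error) or `"add_one"` (add-one smoothing over the phoneme
#'   inventory observed in the lexicon).
#' @return Numeric vector of surprisal values in bits, one per phoneme.
#' @examples
#' lex <- tibble::tibble(word = c("ab", "ac"),
#'                       pronunciation = c("A B", "A C"),
#'                       frequency = c(3L, 1L))
#' surprisal(lex, c("A", "B"))  # 0 and -log2(3/4) bits
#' @export
surprisal <- function(lexicon, pronunciation, smoothing = c("none", "add_one")) {
  smoothing <- match.arg(smoothing)
  if (length(pronunciation) == 1 && grepl(" ", pronunciation)) {
    pronunciation <- strsplit(pronunciation, " ", fixed = TRUE)[[1]]
  }
  k <- length(pronunciation)
  if (!k) return(numeric(0))
  n_symbols <- length(unique(unlist(strsplit(lexicon$pronunciation, " ", fixed = TRUE))))
  out <- numeric(k)
  f_prev <- prefix_frequency(lexicon, character(0))
  for (i in seq_len(k)) {
    f_cur <- prefix_frequency(lexicon, pronunciation[seq_len(i)])
    if (f_cur == 0) {
      if (smoothing == "none") {
        abort(sprintf(
          "prefix '%s' has zero lexicon frequency; use smoothing = \"add_one\" or extend the lexicon",
          paste(pronunciation[seq_len(i)], collapse = " ")))
      }
      out[i] <- -log2((f_cur + 1) / (f_prev + n_symbols))
      f_prev <- f_cur + 1  # continue on the smoothed count
    } else {
      out[i] <- if (smoothing == "add_one") {
        -log2((f_cur + 1) / (f_prev + n_symbols))
      } else {
        -log2(f_cur / f_prev)
      }
      f_prev <- if (smoothing == "add_one") f_cur + 1 else f_cur
    }
  }
  out
}

#' Phonemic-surprisal impulse train
#'
#' An impulse at each phoneme onset scaled by that phoneme's surprisal;
#' the phoneme prefix resets at every word boundary.
#'
#' @param annotation Tibble with columns `phoneme`, `onset_s`,
#'   `word_index`.
#' @param lexicon A lexicon tibble.
#' @param duration_s Series duration in seconds.
#' @param fs Analysis rate in Hz (default 128).
#' @param sentence Sentence identifier.
#' @inheritParams surprisal
#' @return A [feature_series()] named `"Ps"`.
#' @export
surprisal_series <- function(annotation, lexicon, duration_s, fs = 128,
                             smoothing = c("none", "add_one"),
                             sentence = NA_character_) {
  smoothing <- match.arg(smoothing)
  stopifnot(all(c("phoneme", "onset_s", "word_index") %in% names(annotation)))
  n <- ceiling(duration_s * fs)
  v <- numeric(n)
  for (w in unique(annotation$word_index)) {
    rows <- annotation[annotation$word_index == w, , drop = FALSE]
    rows <- rows[order(rows$onset_s), , drop = FALSE]
    s <- surprisal(lexicon, rows$phoneme, smoothing = smoothing)
    idx <- time_to_sample(rows$onset_s, fs) + 1L
    if (any(idx > n)) abort(sprintf("phoneme onset beyond duration in word %s", w))
    v[idx] <- s
  }
  feature_series(v, fs, "Ps", sentence = sentence)
}

#' Semantic dissimilarity of words in context
#'
#' For each word from the second onward, one minus the Pearson
#' correlation between its embedding and the mean embedding of all
#' preceding words in the sentence. The sentence-initial word has no
#' context and is excluded (it emits no value).
#'
#' @param vectors Word-vector matrix (words as rownames; see
#'   [read_vectors()]).
#' @param words Character vector of sentence words in order.
#' @param oov `"skip"` (default: drop out-of-vocabulary words from both
#'   the targets and the context, recording them in the `oov` attribute)
#'   or `"error"`.
#' @return A tibble with columns `position` (index into `words`), `word`
#'   and `dissimilarity` (in `[0, 2]` when the correlation is defined).
#' @export
semantic_dissimilarity <- function(vectors, words, oov = c("skip", "error")) {
  oov <- match.arg(oov)
  known <- words %in% rownames(vectors)
  if (any(!known) && oov == "error") {
    abort(sprintf("words missing from the vector table: %s",
                  paste(unique(words[!known]), collapse = ", ")))
  }
  keep <- which(known)
  out <- tibble(position = integer(), word = character(), dissimilarity = numeric())
  if (length(keep) >= 2) {
    ctx <- NULL
    rows <- vector("list", length(keep) - 1)
    for (j in seq_along(keep)) {
      w <- words[keep[j]]
      v <- vectors[w, ]
      if (j >= 2) {
        rows[[j - 1]] <- tibble(position = keep[j], word = w,
                                dissimilarity = 1 - safe_cor(v, ctx / (j - 1)))
      }
      ctx <- if (is.null(ctx)) v else ctx + v
    }
    out <- bind_rows(rows)
  }
  attr(out, "oov") <- unique(words[!known])
  out
}

#' Semantic-dissimilarity impulse train
#'
#' An impulse at each included word's onset scaled by its semantic
#' dissimilarity; the sentence-initial word emits no impulse.
#'
#' @param annotation Phoneme-level annotation tibble with columns
#'   `onset_s`, `word_index`, `word` (the word onset is the onset of its
#'   first phoneme).
#' @param vectors Word-vector matrix.
#' @param duration_s Series duration in seconds.
#' @param fs Analysis rate in Hz (default 128).
#' @param sentence Sentence identifier.
#' @inheritParams semantic_dissimilarity
#' @return A [feature_series()] named `"Sem"`.
#' @export
semantic_series <- function(annotation, vectors, duration_s, fs = 128,
                            oov = c("skip", "error"), sentence = NA_character_) {
  oov <- match.arg(oov)
  words_tbl <- annotation |>
    group_by(.data$word_index) |>
    summarise(word = .data$word[1], onset_s = min(.data$onset_s), .groups = "drop") |>
    arrange(.data$onset_s)
  dis <- semantic_dissimilarity(vectors, words_tbl$word, oov = oov)
  n <- ceiling(duration_s * fs)
  v <- numeric(n)
  if (nrow(dis)) {
    idx <- time_to_sample(words_tbl$onset_s[dis$position], fs) + 1L
    if (any(idx > n)) abort("word onset beyond duration")
    v[idx] <- dis$dissimilarity
  }
  feature_series(v, fs, "Sem", sentence = sentence)
}
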