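# Synthetic two-group speech-EEG cohorts with known ground truth. Each
# trial is, by construction, the sum over stimulus features of a known
# response kernel convolved with that feature (the envelope kernel scaled
# by a group-specific gain) plus spatially mixed 1/f noise at a stated
# SNR, so every downstream stage can be tested by parameter recovery.

#' Configuration for a simulated listening cohort
#'
#' Defaults mirror the canonical passive-listening design: two groups of
#' 20 subjects, 10 sentences of about 1.8 s each presented 50 times, 64
#' channels, analyzed at 128 Hz, with a multiplicative group gain of 1.5
#' on the envelope response kernel for the non-native group and pink
#' (1/f) background noise at 0 dB SNR.
#'
#' @param n_per_group Subjects per group.
#' @param n_sentences Number of stimulus sentences.
#' @param trials_per_sentence Presentations of each sentence.
#' @param sentence_duration_s,duration_sd_s Mean and SD of sentence
#'   duration (seconds); per-sentence durations are drawn once per cohort.
#' @param n_channels EEG channels.
#' @param fs_hz EEG analysis rate (Hz).
#' @param audio_fs_hz Rate of the synthetic audio carrier (Hz, >= 8000).
#' @param pre_s,post_s Epoch extent before/after stimulus onset (seconds).
#' @param kernel_features Names of the features given response kernels
#'   (any of `"Env"`, `"Pon"`, `"Ps"`, `"Sem"`, or the manner categories
#'   `"vowel"`, `"nasal"`, `"plosive"`, `"fricative"`).
#' @param kernels Optional kernel map (name -> list(lags_ms, weights
#'   `lag x channel`)); defaults are built per cohort. Kernels must be
#'   supported inside the -100..500 ms forward lag window.
#' @param group_gain Named multipliers on the envelope kernel, one per
#'   group.
#' @param noise_snr_db Signal-to-noise ratio in dB (`Inf` for noiseless).
#' @param noise_exponent Spectral slope alpha of the 1/f^alpha noise.
#' @param vector_dim Dimensionality of the toy word embeddings.
#' @param min_gap_s Minimum spacing between phoneme onsets (seconds).
#' @param seed Integer master seed; all cohort randomness derives from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_per_group = 20L,
                       n_sentences = 10L,
                       trials_per_sentence = 50L,
                       sentence_duration_s = 1.8,
                       duration_sd_s = 0.2,
                       n_channels = 64L,
                       fs_hz = 128,
                       audio_fs_hz = 8192,
                       pre_s = 0.5,
                       post_s = 2.5,
                       kernel_features = c("Env", "Pon"),
                       kernels = NULL,
                       group_gain = c(native = 1, nonnative = 1.5),
                       noise_snr_db = 0,
                       noise_exponent = 1,
                       vector_dim = 400L,
                       min_gap_s = 0.04,
                       seed = 1L) {
  if (trials_per_sentence < 1) abort("trials_per_sentence must be at least 1")
  if (audio_fs_hz < 8000) abort("audio_fs_hz must be at least 8000")
  if (is.null(names(group_gain)) || any(!nzchar(names(group_gain)))) {
    abort("group_gain must be a named vector")
  }
  cfg <- list(
    n_per_group = as.integer(n_per_group), n_sentences = as.integer(n_sentences),
    trials_per_sentence = as.integer(trials_per_sentence),
    sentence_duration_s = sentence_duration_s, duration_sd_s = duration_sd_s,
    n_channels = as.integer(n_channels), fs_hz = fs_hz,
    audio_fs_hz = audio_fs_hz, pre_s = pre_s, post_s = post_s,
    kernel_features = kernel_features, kernels = kernels,
    group_gain = group_gain, noise_snr_db = noise_snr_db,
    noise_exponent = noise_exponent, vector_dim = as.integer(vector_dim),
    min_gap_s = min_gap_s, seed = as.integer(seed)
  )
  if (!is.null(kernels)) {
    for (nm in names(kernels)) {
      lg <- kernels[[nm]]$lags_ms
      if (min(lg) < -100 || max(lg) > 500) {
        abort(sprintf("kernel '%s' extends outside the -100..500 ms lag window", nm))
      }
    }
  }
  class(cfg) <- "sim_config"
  cfg
}

# Canonical multiphasic (P1-N1-P2 style) time courses per feature, in ms.
kernel_shape_table <- function() {
  list(
    Env       = list(mu = c(50, 120, 220),  sg = c(12, 25, 40), a = c(0.6, -1.0, 0.7)),
    Pon       = list(mu = c(60, 130, 250),  sg = c(15, 30, 50), a = c(0.5, -0.7, 0.45)),
    Ps        = list(mu = c(150, 300),      sg = c(35, 55),     a = c(-0.5, 0.35)),
    Sem       = list(mu = c(200, 400),      sg = c(45, 60),     a = c(-0.6, 0.3)),
    vowel     = list(mu = c(110, 210),      sg = c(25, 40),     a = c(-0.8, 0.6)),
    nasal     = list(mu = c(140, 260),      sg = c(30, 45),     a = c(-0.7, 0.5)),
    plosive   = list(mu = c(90, 180, 300),  sg = c(20, 35, 50), a = c(-0.9, 0.7, -0.3)),
    fricative = list(mu = c(160, 280),      sg = c(35, 50),     a = c(-0.6, 0.6))
  )
}

kernel_timecourse <- function(name, lags_ms) {
  sh <- kernel_shape_table()[[name]]
  if (is.null(sh)) sh <- list(mu = c(130, 270), sg = c(30, 50), a = c(-0.7, 0.5))
  tc <- numeric(length(lags_ms))
  for (k in seq_along(sh$mu)) {
    tc <- tc + sh$a[k] * exp(-0.5 * ((lags_ms - sh$mu[k]) / sh$sg[k])^2)
  }
  tc
}

# Smooth seeded channel topography with unit RMS.
kernel_topography <- function(n_channels, seed) {
  with_seed(seed, {
    c_idx <- seq_len(n_channels)
    h <- sample(1:3, 2)
    ph <- runif(2, 0, 2 * pi)
    v <- sin(2 * pi * h[1] * c_idx / n_channels + ph[1]) +
      0.5 * sin(2 * pi * h[2] * c_idx / n_channels + ph[2]) +
      0.3
    v / sqrt(mean(v^2))
  })
}

# Smooth seeded per-channel latency shifts (ms), spread +-`spread_ms`,
# emulating the latency gradients of scalp evoked responses.
kernel_latency_map <- function(n_channels, seed, spread_ms = 25) {
  with_seed(seed, {
    c_idx <- seq_len(n_channels)
    ph <- runif(1, 0, 2 * pi)
    v <- sin(2 * pi * c_idx / n_channels + ph)
    v / max(abs(v)) * spread_ms
  })
}

#' Default ground-truth response kernels
#'
#' Builds one kernel per configured feature: a canonical multiphasic time
#' course (distinct per feature) on the -100..500 ms lag grid, projected
#' onto a smooth seeded amplitude topography with a smooth latency
#' gradient (about +-25 ms) across channels, as scalp evoked responses
#' show.
#'
#' @param config A [sim_config()].
#' @return Named list of kernels, each `list(lags_ms, weights)` with
#'   `weights` a `lag x channel` matrix.
#' @export
default_kernels <- function(config) {
  lags <- lag_set(-100, 500, config$fs_hz)
  lags_ms <- lags / config$fs_hz * 1000
  out <- list()
  for (nm in config$kernel_features) {
    topo <- kernel_topography(config$n_channels, child_seed(config$seed, "topo", nm))
    lat <- kernel_latency_map(config$n_channels, child_seed(config$seed, "lat", nm))
    weights <- vapply(seq_len(config$n_channels), function(cc) {
      kernel_timecourse(nm, lags_ms - lat[cc]) * topo[cc]
    }, numeric(length(lags)))
    out[[nm]] <- list(lags_ms = lags_ms, lags = lags, weights = weights)
  }
  out
}

#' Similarity between a fitted TRF and a ground-truth kernel
#'
#' Per-channel Pearson correlation between the fitted and true time
#' courses, averaged over channels with weights proportional to the true
#' kernel's channel RMS. Per-channel correlation is the right recovery
#' metric for models fitted on z-scored data, whose weights carry an
#' arbitrary positive scale per channel; RMS weighting keeps channels
#' that carry essentially no kernel energy (whose correlation is
#' undefined noise) from diluting the summary.
#'
#' @param trf A `forward_trf` (or a `lag x channel` weight matrix).
#' @param kernel A kernel from a [gen_truth()] object
#'   (`list(lags_ms, weights)`) or a `lag x channel` matrix on the same
#'   lag grid.
#' @return RMS-weighted mean per-channel Pearson r.
#' @export
kernel_similarity <- function(trf, kernel) {
  w <- if (inherits(trf, "forward_trf")) trf$weights else as.matrix(trf)
  k <- if (is.list(kernel)) kernel$weights else as.matrix(kernel)
  if (!all(dim(w) == dim(k))) abort("fitted and true kernels differ in shape")
  r_c <- vapply(seq_len(ncol(w)), function(cc) safe_cor(w[, cc], k[, cc]), numeric(1))
  wt <- sqrt(colMeans(k^2))
  if (sum(wt) == 0) abort("true kernel is identically zero")
  sum(r_c * wt, na.rm = TRUE) / sum(wt[!is.na(r_c)])
}

# Raised-cosine bump, support [0, 1].
raised_cosine <- function(s) ifelse(s >= 0 & s <= 1, 0.5 * (1 - cos(2 * pi * s)), 0)

# Evaluate a stored modulator parameterization at times t (seconds).
modulator_eval <- function(par, t) {
  m <- rep(par$base, length(t))
  for (k in seq_along(par$onsets)) {
    m <- m + par$amps[k] * raised_cosine((t - par$onsets[k]) / par$widths[k])
  }
  edge <- 0.02
  ramp_in <- pmin(pmax(t / edge, 0), 1)
  ramp_out <- pmin(pmax((par$duration_s - t) / edge, 0), 1)
  m * ramp_in * ramp_out
}

#' Generate one synthetic sentence
#'
#' Draws a phoneme sequence (labels sampled proportionally to the
#' inventory counts, onsets spaced at least `min_gap_s` apart),
#' partitions it into words of 2-5 phonemes, and synthesizes a
#' multi-tone carrier amplitude-modulated by a known modulator whose
#' parameterization is stored so envelope extraction can be checked
#' against ground truth.
#'
#' @param config A [sim_config()].
#' @param inventory A [phoneme_inventory()].
#' @param seed Integer seed for this sentence.
#' @param duration_s Optional fixed duration; by default drawn from the
#'   configured mean and SD.
#' @return List with `annotation` (tibble: `phoneme`, `manner`,
#'   `onset_s`, `word_index`, `word`), `duration_s`, `modulator`
#'   (parameter list for [modulator_eval()]), `carrier` (tone
#'   frequencies/phases) and `audio` (the modulated waveform at
#'   `audio_fs_hz`).
#' @export
gen_sentence <- function(config, inventory, seed, duration_s = NULL) {
  stopifnot(inherits(inventory, "phoneme_inventory"))
  with_seed(seed, {
    dur <- duration_s %||% max(config$sentence_duration_s - 3 * config$duration_sd_s,
                               min(config$sentence_duration_s + 3 * config$duration_sd_s,
                                   rnorm(1, config$sentence_duration_s, config$duration_sd_s)))
    if (dur < 0.2) abort(sprintf("duration %.3f s is too short to place a phoneme", dur))
    onsets <- numeric(0)
    t <- 0.08
    while (t < dur - 0.12) {
      onsets <- c(onsets, t)
      t <- t + config$min_gap_s + rexp(1, rate = 1 / 0.05)
    }
    if (!length(onsets)) abort(sprintf("duration %.3f s is too short to place a phoneme", dur))
    n_ph <- length(onsets)
    labels <- sample(inventory$phoneme, n_ph, replace = TRUE,
                     prob = inventory$count / sum(inventory$count))
    manner <- inventory$manner[match(labels, inventory$phoneme)]

    # Partition into words of 2-5 phonemes (a leftover single phoneme is
    # absorbed by widening the preceding word's draw).
    sizes <- integer(0)
    remaining <- n_ph
    while (remaining > 0) {
      s <- if (remaining <= 5) {
        remaining
      } else if (remaining == 6) {
        3L
      } else {
        s0 <- sample(2:5, 1)
        if (remaining - s0 == 1) s0 + ifelse(s0 < 5, 1L, -1L) else s0
      }
      sizes <- c(sizes, s)
      remaining <- remaining - s
    }
    word_index <- rep(seq_along(sizes), times = sizes)
    word <- vapply(split(labels, word_index),
                   function(p) tolower(paste(p, collapse = "-")), character(1))
    annotation <- tibble(
      phoneme = labels, manner = manner, onset_s = onsets,
      word_index = word_index, word = unname(word[word_index])
    )

    modulator <- list(
      onsets = onsets,
      amps = runif(n_ph, 0.6, 1.0),
      widths = runif(n_ph, 0.08, 0.14),
      base = 0.15,
      duration_s = dur
    )
    n_tones <- 12L
    carrier <- list(
      freqs = seq(300, 3100, length.out = n_tones) + runif(n_tones, -30, 30),
      phases = runif(n_tones, 0, 2 * pi)
    )
    t_audio <- seq(0, dur - 1 / config$audio_fs_hz, by = 1 / config$audio_fs_hz)
    carrier_wave <- rowSums(vapply(seq_len(n_tones), function(k) {
      sin(2 * pi * carrier$freqs[k] * t_audio + carrier$phases[k])
    }, numeric(length(t_audio)))) / sqrt(n_tones)
    audio <- carrier_wave * modulator_eval(modulator, t_audio)

    list(annotation = annotation, duration_s = dur, modulator = modulator,
         carrier = carrier, audio = audio)
  })
}

#' Toy pronunciation lexicon and word vectors
#'
#' `gen_toy_lexicon()` samples word forms of 2-5 phonemes over an
#' inventory (draw probabilities proportional to the inventory counts)
#' with Zipf-like positive integer frequencies. `gen_toy_vectors()` draws
#' Gaussian word embeddings of a fixed dimension.
#'
#' @param inventory A [phoneme_inventory()].
#' @param n_words Number of words (at least 2).
#' @param seed Integer seed.
#' @return `gen_toy_lexicon()`: a lexicon tibble (`word`,
#'   `pronunciation`, `frequency`); `gen_toy_vectors()`: a matrix with
#'   words as rownames.
#' @export
gen_toy_lexicon <- function(inventory, n_words = 50L, seed = 1L) {
  if (n_words < 2) abort("n_words must be at least 2")
  with_seed(seed, {
    prons <- character(0)
    guard <- 0L
    while (length(prons) < n_words && guard < 50L * n_words) {
      len <- sample(2:5, 1)
      p <- sample(inventory$phoneme, len, replace = TRUE,
                  prob = inventory$count / sum(inventory$count))
      prons <- unique(c(prons, paste(p, collapse = " ")))
      guard <- guard + 1L
    }
    prons <- prons[seq_len(min(n_words, length(prons)))]
    ranks <- sample(seq_along(prons))
    tibble(
      word = tolower(gsub(" ", "-", prons, fixed = TRUE)),
      pronunciation = prons,
      frequency = as.integer(pmax(1, round(2 * length(prons) / ranks)))
    )
  })
}

#' @rdname gen_toy_lexicon
#' @param words Character vector of words.
#' @param dim Embedding dimension (at least 2).
#' @export
gen_toy_vectors <- function(words, dim = 400L, seed = 1L) {
  if (dim < 2) abort("dim must be at least 2")
  with_seed(seed, {
    m <- matrix(rnorm(length(words) * dim), nrow = length(words),
                dimnames = list(words, NULL))
    validate_vectors(m, source = "gen_toy_vectors")
  })
}

#' Ground truth for a simulated cohort
#'
#' Generates the sentences, lexicon, word vectors, response kernels and
#' per-sentence feature series of a cohort, plus the per-feature noiseless
#' response components from which every trial is later assembled. The
#' returned object is sufficient to recompute any generated trial exactly.
#'
#' @param config A [sim_config()].
#' @param inventory A [phoneme_inventory()] (default: the bundled English
#'   set).
#' @return An object of class `sim_truth`.
#' @export
gen_truth <- function(config, inventory = default_inventory("english")) {
  fs <- config$fs_hz
  sentences <- lapply(seq_len(config$n_sentences), function(s) {
    out <- gen_sentence(config, inventory, child_seed(config$seed, "sentence", s))
    out$id <- sprintf("s%02d", s)
    out
  })
  names(sentences) <- vapply(sentences, `[[`, character(1), "id")

  # Lexicon: every sentence word, plus toy distractors, Zipf frequencies.
  sent_words <- unique(bind_rows(lapply(sentences, function(s) {
    s$annotation |>
      group_by(.data$word_index) |>
      summarise(word = .data$word[1],
                pronunciation = paste(.data$phoneme, collapse = " "),
                .groups = "drop") |>
      select("word", "pronunciation")
  })))
  extras <- gen_toy_lexicon(inventory, n_words = max(20L, nrow(sent_words)),
                            seed = child_seed(config$seed, "lexicon"))
  lex <- bind_rows(
    mutate(sent_words, frequency = 1L),
    select(extras, "word", "pronunciation", "frequency")
  )
  lex <- lex[!duplicated(lex$word), , drop = FALSE]
  lex$frequency <- with_seed(child_seed(config$seed, "freq"), {
    as.integer(pmax(1, round(3 * nrow(lex) / sample(seq_len(nrow(lex))))))
  })
  lexicon <- as_lexicon(lex, inventory = inventory, source = "sim lexicon")
  vectors <- gen_toy_vectors(lexicon$word, dim = config$vector_dim,
                             seed = child_seed(config$seed, "vectors"))

  kernels <- config$kernels %||% default_kernels(config)
  n_pre <- round(config$pre_s * fs)
  n_post <- round(config$post_s * fs)

  features <- list()
  responses <- list()
  for (s in names(sentences)) {
    sn <- sentences[[s]]
    dur <- sn$duration_s
    ann <- sn$annotation
    t_post <- (seq_len(n_post) - 1) / fs
    env <- modulator_eval(sn$modulator, t_post)
    env[t_post >= dur] <- 0
    fl <- list(Env = feature_series(env, fs, "Env", s))
    fl$Pon <- {
      po <- fit_feature_vector(phoneme_onsets(ann, dur, fs, s), n_post)
      feature_series(po, fs, "Pon", s)
    }
    fl$Ps <- {
      ps <- fit_feature_vector(surprisal_series(ann, lexicon, dur, fs, sentence = s), n_post)
      feature_series(ps, fs, "Ps", s)
    }
    fl$Sem <- {
      se <- fit_feature_vector(semantic_series(ann, vectors, dur, fs, sentence = s), n_post)
      feature_series(se, fs, "Sem", s)
    }
    for (mn in intersect(manner_levels(), names(kernels))) {
      tr <- fit_feature_vector(
        phoneme_onsets(ann[ann$manner == mn, , drop = FALSE], dur, fs, s), n_post)
      fl[[mn]] <- feature_series(tr, fs, mn, s)
    }
    features[[s]] <- fl

    resp <- list()
    for (nm in names(kernels)) {
      if (is.null(fl[[nm]])) {
        abort(sprintf("kernel '%s' has no matching feature series", nm))
      }
      full <- c(numeric(n_pre), fl[[nm]]$values)
      X <- lag_matrix(full, kernels[[nm]]$lags)
      resp[[nm]] <- X %*% kernels[[nm]]$weights
    }
    responses[[s]] <- resp
  }

  structure(list(
    config = config, inventory = inventory, sentences = sentences,
    lexicon = lexicon, vectors = vectors, kernels = kernels,
    features = features, responses = responses,
    group_gain = config$group_gain
  ), class = "sim_truth")
}

# Noiseless signal (samples x channels) for one sentence and group.
# `group = NULL` gives the unit-gain reference response.
truth_signal <- function(truth, sentence, group = NULL) {
  if (!is.null(group) && !group %in% names(truth$group_gain)) {
    abort(sprintf("group '%s' has no gain entry", group))
  }
  gain <- if (is.null(group)) 1 else truth$group_gain[[group]]
  resp <- truth$responses[[sentence]]
  sig <- 0
  for (nm in names(resp)) {
    g <- if (nm == "Env") gain else 1
    sig <- sig + g * resp[[nm]]
  }
  sig
}

#' Generate the trials of one simulated subject
#'
#' Assembles each trial as the group-gained sum of kernel-convolved
#' feature responses plus spatially mixed 1/f noise scaled to the
#' configured SNR. The SNR is defined per sentence as the unit-gain
#' reference signal power over the expected noise power (all channels
#' and samples of the epoch), so the noise floor is shared across
#' groups and a group gain genuinely raises the response above it.
#' Trials of one sentence differ only in their noise; noise draws depend
#' on the subject seed, sentence and trial, never on the group, so
#' matched seeds isolate the group gain.
#'
#' @param truth A [gen_truth()] object.
#' @param group Group name (must have a `group_gain` entry).
#' @param subject_seed Integer seed for this subject.
#' @param sentences Optional subset of sentence ids.
#' @return Named list of [trial_set()]s, one per sentence.
#' @export
gen_subject_trials <- function(truth, group, subject_seed, sentences = NULL) {
  cfg <- truth$config
  fs <- cfg$fs_hz
  n_ch <- cfg$n_channels
  sentences <- sentences %||% names(truth$sentences)
  mix <- with_seed(child_seed(subject_seed, "mix"), random_orthonormal(n_ch))
  layout <- sensor_layout(n_ch)
  out <- list()
  for (s in sentences) {
    sig <- truth_signal(truth, s, group)
    n_samp <- nrow(sig)
    # The noise floor is group-independent: SNR is defined against the
    # unit-gain reference response, so a group gain raises the signal
    # above a shared background rather than rescaling the whole trial.
    p_ref <- mean(truth_signal(truth, s)^2)
    sd_noise <- if (is.infinite(cfg$noise_snr_db)) 0 else {
      sqrt(p_ref * 10^(-cfg$noise_snr_db / 10))
    }
    dat <- array(0, dim = c(cfg$trials_per_sentence, n_ch, n_samp))
    for (j in seq_len(cfg$trials_per_sentence)) {
      trial <- sig
      if (sd_noise > 0) {
        noise <- with_seed(child_seed(subject_seed, "noise", s, j), {
          e <- vapply(seq_len(n_ch), function(cc) pink_noise(n_samp, cfg$noise_exponent),
                      numeric(n_samp))
          e %*% t(mix)
        })
        trial <- trial + sd_noise * noise
      }
      dat[j, , ] <- t(trial)
    }
    out[[s]] <- trial_set(dat, fs, pre_s = cfg$pre_s, sentence = s,
                          positions = layout, units = "uV")
  }
  out
}

#' Generate a two-group cohort
#'
#' Builds the shared ground truth and the subject table of a cohort; the
#' trials of any subject are materialized on demand with
#' [cohort_trials()], keeping large cohorts memory-light.
#'
#' @param config A [sim_config()].
#' @param inventory A [phoneme_inventory()].
#' @return An object of class `sim_cohort`: `truth` plus a `subjects`
#'   tibble (`subject`, `group`, `seed`).
#' @export
gen_cohort <- function(config, inventory = default_inventory("english")) {
  truth <- gen_truth(config, inventory)
  groups <- names(config$group_gain)
  subjects <- bind_rows(lapply(groups, function(g) {
    tibble(
      subject = sprintf("%s%02d", g, seq_len(config$n_per_group)),
      group = g
    )
  }))
  subjects$seed <- vapply(subjects$subject, function(id) {
    child_seed(config$seed, "subject", id)
  }, integer(1))
  structure(list(truth = truth, subjects = subjects), class = "sim_cohort")
}

#' @rdname gen_cohort
#' @param cohort A `sim_cohort`.
#' @param subject A subject id from `cohort$subjects`.
#' @param sentences Optional subset of sentence ids.
#' @export
cohort_trials <- function(cohort, subject, sentences = NULL) {
  row <- cohort$subjects[cohort$subjects$subject == subject, , drop = FALSE]
  if (!nrow(row)) abort(sprintf("unknown subject '%s'", subject))
  gen_subject_trials(cohort$truth, row$group[1], row$seed[1], sentences = sentences)
}

#' Effective per-phoneme utterance counts of a cohort
#'
#' The number of occurrences of each phoneme across the sentence set
#' multiplied by the number of presentations per sentence: the count of
#' epochs that enter each phoneme's averaged response.
#'
#' @param truth A [gen_truth()] object.
#' @return Tibble with `phoneme`, `manner`, `occurrences`, `effective`.
#' @export
effective_counts <- function(truth) {
  ann <- bind_rows(lapply(truth$sentences, `[[`, "annotation"))
  ann |>
    group_by(.data$phoneme, .data$manner) |>
    summarise(occurrences = dplyr::n(), .groups = "drop") |>
    mutate(effective = .data$occurrences * truth$config$trials_per_sentence) |>
    arrange(desc(.data$effective))
}

#' Approximate circular sensor layout
#'
#' Places `n` sensors on concentric rings of the unit disk, a generic
#' 2-D cap layout used for distance-based channel interpolation.
#'
#' @param n Number of channels.
#' @return An `n x 2` matrix of x/y positions.
#' @export
sensor_layout <- function(n) {
  n_rings <- max(1L, ceiling(sqrt(n / 3)))
  radii <- seq(0.25, 1, length.out = n_rings)
  per_ring <- diff(round(seq(0, n, length.out = n_rings + 1)))
  pos <- matrix(0, 0, 2)
  for (r in seq_len(n_rings)) {
    k <- per_ring[r]
    if (k == 0) next
    th <- 2 * pi * (seq_len(k) - 1) / k + 0.2 * r
    pos <- rbind(pos, cbind(radii[r] * cos(th), radii[r] * sin(th)))
  }
  pos[seq_len(n), , drop = FALSE]
}
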