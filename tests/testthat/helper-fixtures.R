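# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Two-word lexicon used by the surprisal worked examples.
toy_lexicon <- function() {
  tibble::tibble(word = c("ab", "ac"),
                 pronunciation = c("A B", "A C"),
                 frequency = c(3L, 1L))
}

tiny_inventory <- function() {
  phoneme_inventory(c("A", "B", "S", "N"),
                    c("vowel", "plosive", "fricative", "nasal"),
                    c(40, 30, 20, 10))
}

# Small noiseless envelope-only cohort truth (8 ch, 3 sentences).
fix_truth_noiseless <- function() {
  cached("truth_noiseless", function() {
    cfg <- sim_config(n_per_group = 2, n_sentences = 3, trials_per_sentence = 5,
                      n_channels = 8, noise_snr_db = Inf,
                      kernel_features = "Env", seed = 42)
    truth <- gen_truth(cfg, default_inventory("english"))
    list(truth = truth,
         trials = gen_subject_trials(truth, "native", 7),
         features = lapply(truth$features, `[[`, "Env"))
  })
}

# Matching noisy (0 dB) cohort from the same truth.
fix_trials_snr0 <- function() {
  cached("trials_snr0", function() {
    cfg <- sim_config(n_per_group = 2, n_sentences = 3, trials_per_sentence = 5,
                      n_channels = 8, noise_snr_db = 0,
                      kernel_features = "Env", seed = 42)
    truth <- gen_truth(cfg, default_inventory("english"))
    list(truth = truth,
         trials = gen_subject_trials(truth, "native", 7),
         features = lapply(truth$features, `[[`, "Env"))
  })
}

# A deterministic trial_set built from an explicit array.
make_trial_set <- function(data, fs = 128, pre_s = 0.5, ...) {
  trial_set(data, fs = fs, pre_s = pre_s, ...)
}
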