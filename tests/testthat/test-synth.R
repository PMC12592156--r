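cfg_small <- sim_config(n_per_group = 2, n_sentences = 2, trials_per_sentence = 5,
                        n_channels = 6, noise_snr_db = 0,
                        kernel_features = "Env", seed = 11)

test_that("gen_sentence places well-formed annotations deterministically", {
  inv <- tiny_inventory()
  s1 <- gen_sentence(cfg_small, inv, seed = 5, duration_s = 1.8)
  s2 <- gen_sentence(cfg_small, inv, seed = 5, duration_s = 1.8)
  expect_identical(s1$annotation, s2$annotation)
  expect_identical(s1$audio, s2$audio)
  ann <- s1$annotation
  expect_true(all(ann$onset_s >= 0 & ann$onset_s < 1.8))
  expect_true(all(diff(ann$onset_s) >= cfg_small$min_gap_s - 1e-12))
  sizes <- table(ann$word_index)
  expect_true(all(sizes >= 2 & sizes <= 5))
  expect_true(all(ann$manner %in% c("vowel", "nasal", "plosive", "fricative")))
})

test_that("too-short sentences are an explicit error", {
  expect_error(gen_sentence(cfg_small, tiny_inventory(), seed = 1, duration_s = 0.05),
               "too short")
})

test_that("phoneme draw frequencies follow the inventory proportions", {
  inv <- tiny_inventory()
  cfg <- sim_config(sentence_duration_s = 4, duration_sd_s = 0, seed = 1)
  draws <- character(0)
  i <- 0L
  while (length(draws) < 10000) {
    i <- i + 1L
    draws <- c(draws, gen_sentence(cfg, inv, seed = i)$annotation$phoneme)
  }
  draws <- draws[1:10000]
  obs <- table(factor(draws, levels = inv$phoneme))
  gf <- suppressWarnings(chisq.test(obs, p = inv$count / sum(inv$count)))
  expect_gt(gf$p.value, 0.01)
})

test_that("effective utterance counts are occurrences times presentations", {
  truth <- fix_truth_noiseless()$truth
  ec <- effective_counts(truth)
  expect_identical(ec$effective, ec$occurrences * truth$config$trials_per_sentence)
  # a phoneme occurring once across the sentence set is seen 50 times when
  # each sentence is presented 50 times
  cfg50 <- sim_config(n_sentences = 2, trials_per_sentence = 50,
                      n_channels = 4, seed = 3)
  ec50 <- effective_counts(gen_truth(cfg50, default_inventory("english")))
  expect_true(all(ec50$effective %% 50 == 0))
  expect_identical(min(ec50$effective[ec50$occurrences == 1]), 50L)
  # conservation: summed effective counts = sentences' phonemes x trials
  n_ph <- sum(ec50$occurrences)
  expect_identical(sum(ec50$effective), n_ph * 50L)
})

test_that("noiseless trials equal the stored kernel responses exactly", {
  fx <- fix_truth_noiseless()
  ts <- fx$trials[[1]]
  sig <- speechtrack:::truth_signal(fx$truth, "s01", "native")
  for (i in seq_len(dim(ts$data)[1])) {
    expect_equal(t(ts$data[i, , ]), sig, tolerance = 1e-12)
  }
})

test_that("a single onset with a unit-impulse feature reproduces the kernel", {
  cfg <- sim_config(n_channels = 4, noise_snr_db = Inf,
                    kernel_features = "Pon", seed = 2, n_sentences = 1,
                    trials_per_sentence = 1)
  truth <- gen_truth(cfg, default_inventory("english"))
  s <- names(truth$sentences)[1]
  # replace the Pon series with a single impulse and rebuild the response
  n_post <- round(cfg$post_s * cfg$fs_hz)
  n_pre <- round(cfg$pre_s * cfg$fs_hz)
  imp <- numeric(n_post)
  k0 <- 40L  # onset sample (0-based) past the lag window
  imp[k0 + 1L] <- 1
  truth$features[[s]]$Pon <- feature_series(imp, cfg$fs_hz, "Pon", s)
  full <- c(numeric(n_pre), imp)
  truth$responses[[s]]$Pon <-
    lag_matrix(full, truth$kernels$Pon$lags) %*% truth$kernels$Pon$weights
  st <- gen_subject_trials(truth, "native", 4)[[s]]
  trial <- t(st$data[1, , ])
  K <- truth$kernels$Pon
  rows <- n_pre + k0 + K$lags + 1L
  expect_equal(trial[rows, ], K$weights, tolerance = 1e-12,
               ignore_attr = TRUE)
  off <- setdiff(seq_len(nrow(trial)), rows)
  expect_true(all(abs(trial[off, ]) < 1e-12))
})

test_that("group gain rescales noiseless trials exactly", {
  fx <- fix_truth_noiseless()
  a <- gen_subject_trials(fx$truth, "native", 7)[[1]]
  b <- gen_subject_trials(fx$truth, "nonnative", 7)[[1]]
  expect_equal(b$data, 1.5 * a$data, tolerance = 1e-12)
  expect_error(gen_subject_trials(fx$truth, "martian", 7), "no gain entry")
})

test_that("realized SNR matches the configured level within 5%", {
  cfg <- sim_config(n_sentences = 1, trials_per_sentence = 50, n_channels = 8,
                    noise_snr_db = 0, kernel_features = "Env", seed = 9)
  truth <- gen_truth(cfg, default_inventory("english"))
  st <- gen_subject_trials(truth, "native", 4)[[1]]
  sig <- speechtrack:::truth_signal(truth, "s01", "native")
  noise_pow <- mean(vapply(seq_len(50), function(j) {
    mean((t(st$data[j, , ]) - sig)^2)
  }, numeric(1)))
  expect_lt(abs(mean(sig^2) / noise_pow - 1), 0.05)
})

test_that("regenerating a cohort from its config and seeds is bit-identical", {
  fx <- fix_trials_snr0()
  again <- gen_subject_trials(fx$truth, "native", 7)
  expect_identical(fx$trials[[1]]$data, again[[1]]$data)
  expect_identical(fx$trials[[3]]$data, again[[3]]$data)
  # trials of one sentence differ only in noise
  sig <- speechtrack:::truth_signal(fx$truth, "s01", "native")
  resid <- apply(fx$trials[[1]]$data, 1, function(m) mean((m - t(sig))^2))
  expect_true(all(resid > 0))
})

test_that("toy lexicon and vectors meet their contracts", {
  inv <- tiny_inventory()
  lex <- gen_toy_lexicon(inv, n_words = 30, seed = 8)
  expect_identical(lex, gen_toy_lexicon(inv, n_words = 30, seed = 8))
  expect_true(all(lex$frequency >= 1))
  syms <- unique(unlist(strsplit(lex$pronunciation, " ")))
  expect_true(all(syms %in% inv$phoneme))
  expect_error(gen_toy_lexicon(inv, n_words = 1), "at least 2")
  vec <- gen_toy_vectors(lex$word, dim = 400, seed = 8)
  expect_identical(dim(vec), c(nrow(lex), 400L))
  expect_true(all(apply(vec, 1, var) > 0))
  expect_error(gen_toy_vectors("a", dim = 1), "at least 2")
})

test_that("configuration guards fire", {
  expect_error(sim_config(trials_per_sentence = 0), "at least 1")
  expect_error(sim_config(group_gain = c(1, 1.5)), "named")
  bad_k <- list(Env = list(lags_ms = seq(-200, 500, by = 10)))
  expect_error(sim_config(kernels = bad_k), "lag window")
})
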