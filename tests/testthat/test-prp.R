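test_that("channel z-normalization is exact over the concatenated trials", {
  set.seed(12)
  tl <- list(a = make_trial_set(array(rnorm(2 * 3 * 50, 5, 2), c(2, 3, 50))),
             b = make_trial_set(array(rnorm(4 * 3 * 50, -1, 7), c(4, 3, 50))))
  z <- znorm_channels(tl)
  for (j in 1:3) {
    all_vals <- c(tl_vals <- c(z$a$data[, j, ], z$b$data[, j, ]))
    expect_lt(abs(mean(all_vals)), 1e-10)
    expect_lt(abs(mean(all_vals^2) - 1), 1e-10)
  }
  expect_identical(z$a$units, "z")
  flat_arr <- array(0, c(1, 2, 20))
  flat_arr[1, 1, ] <- 3
  flat_arr[1, 2, ] <- rnorm(20)
  expect_error(znorm_channels(make_trial_set(flat_arr)), "ch01")
  # near-standard-normal input is changed only slightly
  big <- make_trial_set(array(rnorm(2 * 2 * 5000), c(2, 2, 5000)))
  zb <- znorm_channels(big)
  expect_gt(cor(as.vector(zb$data), as.vector(big$data)), 0.999)
})

test_that("phoneme epoch bookkeeping is conserved", {
  fx <- fix_trials_snr0()
  ann <- lapply(fx$truth$sentences, `[[`, "annotation")
  z <- znorm_channels(fx$trials)
  ep <- epoch_phonemes(z, ann)
  prp <- average_prp(ep)
  ec <- effective_counts(fx$truth)
  total_expected <- sum(ec$effective) - ep$dropped_epochs
  expect_identical(sum(prp$counts), as.integer(total_expected))
  expect_identical(sum(prp$category_counts), sum(prp$counts))
  # per-phoneme counts match occurrences x retained trials for kept onsets
  expect_identical(length(prp$time_ms),
                   as.integer(round(0.55 * 128)) + 1L)
})

test_that("onsets whose window leaves the trial are dropped and logged", {
  ann <- tibble::tibble(phoneme = c("A", "B"), manner = c("vowel", "plosive"),
                        onset_s = c(0.5, 2.3))  # 2.3 s: window end beyond trial
  dat <- array(rnorm(2 * 2 * 384), c(2, 2, 384))
  ts <- make_trial_set(dat)
  ep <- epoch_phonemes(ts, ann)
  expect_identical(names(ep$stacks), "A")
  expect_identical(ep$dropped_epochs, 2L)
  expect_identical(dim(ep$stacks$A)[1], 2L)
  # a planted impulse at the onset appears at epoch time zero
  dat2 <- array(0, c(1, 2, 384))
  on_idx <- 64L + speechtrack:::time_to_sample(0.5, 128)
  dat2[1, , on_idx + 1L] <- 9
  ep2 <- epoch_phonemes(make_trial_set(dat2), ann[1, ])
  t0 <- which(abs(ep2$time_ms) < 1e-9)
  expect_equal(ep2$stacks$A[1, 1, t0], 9)
})

test_that("averaging identical epochs returns the epoch itself", {
  kern <- outer(sin(seq(0, 3, length.out = 71)), c(1, -0.5))
  dat <- array(0, c(5, 2, 384))
  ann <- tibble::tibble(phoneme = "A", manner = "vowel", onset_s = 0.8)
  on <- 64L + speechtrack:::time_to_sample(0.8, 128)
  for (i in 1:5) dat[i, , (on - 6 + 1):(on + 64 + 1)] <- t(kern)
  ep <- epoch_phonemes(make_trial_set(dat), ann)
  prp <- average_prp(ep)
  expect_gt(cor(as.vector(prp$phoneme$A), as.vector(t(kern))), 0.999)
  expect_identical(unname(prp$counts["A"]), 5L)
})

test_that("grand average via categories equals the direct epoch-weighted mean", {
  fx <- fix_trials_snr0()
  ann <- lapply(fx$truth$sentences, `[[`, "annotation")
  prp <- average_prp(epoch_phonemes(znorm_channels(fx$trials), ann))
  via_cat <- Reduce(`+`, lapply(names(prp$category), function(mn) {
    colMeans(prp$category[[mn]]) * prp$category_counts[mn]
  })) / sum(prp$category_counts)
  expect_equal(unname(via_cat), unname(prp$grand), tolerance = 1e-12)
})

test_that("PRP noise floor shrinks as one over the square root of N", {
  set.seed(6)
  dat <- array(rnorm(1000 * 8 * 384), c(1000, 8, 384))
  ann <- tibble::tibble(phoneme = "A", manner = "vowel", onset_s = 1.0)
  rms <- vapply(c(10, 100, 1000), function(n) {
    ts <- make_trial_set(dat[seq_len(n), , , drop = FALSE])
    prp <- average_prp(epoch_phonemes(ts, ann))
    sqrt(mean(prp$phoneme$A^2))
  }, numeric(1))
  slope <- coef(lm(log10(rms) ~ log10(c(10, 100, 1000))))[2]
  expect_lt(abs(slope + 0.5), 0.05)
})

test_that("distinct category kernels are recovered by their own category PRPs", {
  cfg <- sim_config(n_per_group = 1, n_sentences = 6, trials_per_sentence = 20,
                    n_channels = 6, noise_snr_db = 0, min_gap_s = 0.5,
                    kernel_features = c("vowel", "plosive"), seed = 17)
  truth <- gen_truth(cfg, phoneme_inventory(c("A", "B"), c("vowel", "plosive"),
                                            c(50, 50)))
  st <- gen_subject_trials(truth, "native", 3)
  ann <- lapply(truth$sentences, `[[`, "annotation")
  prp <- average_prp(epoch_phonemes(znorm_channels(st), ann))
  keep <- truth$kernels$vowel$lags_ms >= min(prp$time_ms) - 1e-6
  r_own <- c(
    kernel_similarity(t(prp$category$vowel), truth$kernels$vowel$weights[keep, ]),
    kernel_similarity(t(prp$category$plosive), truth$kernels$plosive$weights[keep, ])
  )
  r_cross <- c(
    kernel_similarity(t(prp$category$vowel), truth$kernels$plosive$weights[keep, ]),
    kernel_similarity(t(prp$category$plosive), truth$kernels$vowel$weights[keep, ])
  )
  expect_true(all(r_own > 0.9))
  expect_true(all(r_own > r_cross))
})

test_that("grand-average similarity behaves like a correlation", {
  fx <- fix_trials_snr0()
  ann <- lapply(fx$truth$sentences, `[[`, "annotation")
  prp <- average_prp(epoch_phonemes(znorm_channels(fx$trials), ann))
  expect_equal(prp_similarity(prp, prp), 1)
  flipped <- prp
  flipped$grand <- -prp$grand
  expect_equal(prp_similarity(prp, flipped), -1)
  # independent noise cohorts correlate near zero on average
  set.seed(20)
  rs <- replicate(30, {
    a <- rnorm(71)
    b <- rnorm(71)
    prp_similarity(a, b)
  })
  expect_lt(abs(mean(rs)), 0.1)
  expect_error(prp_similarity(rnorm(10), rnorm(12)), "length")
})

test_that("prp tidiers summarize phonemes and categories", {
  fx <- fix_trials_snr0()
  ann <- lapply(fx$truth$sentences, `[[`, "annotation")
  prp <- average_prp(epoch_phonemes(znorm_channels(fx$trials), ann))
  td <- tidy(prp)
  expect_identical(nrow(td), length(prp$phoneme) * length(prp$time_ms))
  expect_s3_class(autoplot(prp), "ggplot")
  gl <- glance(prp)
  expect_identical(gl$n_epochs, sum(prp$counts))
})
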