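test_that("lag_matrix shifts series per the forward-model convention", {
  x <- numeric(10)
  x[5] <- 1
  X <- lag_matrix(x, 0:2)
  expect_identical(dim(X), c(10L, 3L))
  expect_equal(X[5:7, ], diag(3))
  expect_true(all(X[-(5:7), ] == 0))
  # zero lag only: the design is the series itself
  expect_equal(lag_matrix(x, 0L)[, 1], x)
  # column count = lags x channels; negative lags advance the series
  m <- cbind(x, rev(x))
  expect_identical(ncol(lag_matrix(m, -2:3)), 12L)
  Xn <- lag_matrix(x, -1L)
  expect_equal(Xn[4, 1], 1)
  expect_error(lag_matrix(x, 0:10), "longer than the series")
})

test_that("ridge_solve agrees with a brute-force normal-equations oracle", {
  set.seed(31)
  for (rep in 1:5) {
    X <- matrix(rnorm(20 * 6), 20, 6)
    Y <- matrix(rnorm(20 * 2), 20, 2)
    for (lambda in c(0, 0.5, 10)) {
      fit <- ridge_solve(X, Y, lambda)
      # oracle: explicit augmented system with an unpenalized intercept
      Xa <- cbind(1, X)
      m <- mean(diag(crossprod(sweep(X, 2, colMeans(X)))))
      P <- diag(c(0, rep(lambda * m, 6)))
      w_full <- solve(crossprod(Xa) + P, crossprod(Xa, Y))
      expect_equal(unname(fit$weights), unname(w_full[-1, , drop = FALSE]),
                   tolerance = 1e-8)
      expect_equal(unname(fit$bias), unname(w_full[1, ]), tolerance = 1e-8)
    }
  }
})

test_that("kernel (dual) and primal ridge paths agree when p > n", {
  set.seed(8)
  X <- matrix(rnorm(15 * 40), 15, 40)
  y <- rnorm(15)
  dual <- ridge_solve(X, y, 2)          # p > n path
  Xa <- cbind(1, X)
  m <- mean(diag(crossprod(sweep(X, 2, colMeans(X)))))
  P <- diag(c(0, rep(2 * m, 40)))
  w_full <- solve(crossprod(Xa) + P, crossprod(Xa, y))
  expect_equal(as.numeric(dual$weights), as.numeric(w_full[-1]), tolerance = 1e-8)
})

test_that("ridge recovers exact coefficients and shrinks monotonically", {
  set.seed(5)
  X <- matrix(rnorm(100 * 6), 100, 6)
  w0 <- rnorm(6)
  Y <- X %*% w0
  fit <- ridge_solve(X, Y, 1e-10)
  expect_equal(as.numeric(fit$weights), w0, tolerance = 1e-6)
  norms <- vapply(10^seq(-1, 9, by = 2), function(l) {
    sqrt(sum(ridge_solve(X, Y, l)$weights^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[length(norms)], 1e-3 * norms[1])
})

test_that("orthonormal designs give the closed-form half-projection at lambda = m", {
  set.seed(7)
  Z <- scale(matrix(rnorm(50 * 4), 50, 4), scale = FALSE)
  X <- qr.Q(qr(Z)) # orthonormal; columns stay orthogonal to the 1-vector
  y <- rnorm(50)
  m <- mean(diag(crossprod(X)))
  fit <- ridge_solve(X, y, 1)  # lambda * m = m since m = colSums = 1
  expect_equal(as.numeric(fit$weights), as.numeric(crossprod(X, y) / 2),
               tolerance = 1e-10)
})

test_that("forward TRF recovers the injected kernel", {
  fx <- fix_truth_noiseless()
  fw <- fit_forward(fx$trials, fx$features)
  expect_gt(kernel_similarity(fw, fx$truth$kernels$Env), 0.99)
  expect_gt(mean(fw$prediction_r), 0.95)
  expect_true(fw$lambda %in% fw$lambda_grid)
  expect_true(all(abs(fw$prediction_r) <= 1))
  # at 0 dB with 50 trials the kernel is still recovered
  nz <- fix_trials_snr0()
  cfg50 <- sim_config(n_per_group = 1, n_sentences = 2, trials_per_sentence = 25,
                      n_channels = 8, noise_snr_db = 0,
                      kernel_features = "Env", seed = 42)
  tr50 <- gen_truth(cfg50, default_inventory("english"))
  st50 <- gen_subject_trials(tr50, "native", 7)
  fw50 <- fit_forward(st50, lapply(tr50$features, `[[`, "Env"))
  expect_gt(kernel_similarity(fw50, tr50$kernels$Env), 0.95)
})

test_that("prediction r on pure-noise trials is near zero", {
  fx <- fix_truth_noiseless()
  set.seed(99)
  rs <- vapply(1:8, function(k) {
    noise <- array(rnorm(5 * 8 * 384), dim = c(5, 8, 384))
    st <- make_trial_set(noise, sentence = "s01")
    fw <- fit_forward(list(s01 = st), fx$features["s01"])
    mean(fw$prediction_r)
  }, numeric(1))
  expect_true(mean(abs(rs) < 0.1) >= 7 / 8)
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("averaging per-trial TRFs equals a single fit for identical trials", {
  fx <- fix_truth_noiseless()
  ts <- fx$trials[[1]]
  fe <- fx$features[[1]]
  fw <- fit_forward(list(s01 = ts), list(s01 = fe))
  # identical noiseless trials: the averaged TRF equals any single-trial fit
  Y <- scale(speechtrack:::trial_matrix(ts, 1, post_only = TRUE))
  fz <- as.numeric(scale(fe$values))
  X <- lag_matrix(fz, fw$lags)
  m1 <- ridge_solve(X, Y, fw$lambda)
  expect_equal(unname(fw$weights), unname(m1$weights), tolerance = 1e-8)
})

test_that("predict_eeg returns signed perfect correlations for (anti)identical data", {
  fx <- fix_truth_noiseless()
  fw <- fit_forward(fx$trials, fx$features)
  pr <- predict_eeg(fw, fx$features[[1]])
  same <- predict_eeg(fw, fx$features[[1]], observed = pr$predicted)
  expect_equal(unname(same$r), rep(1, 8), tolerance = 1e-12)
  anti <- predict_eeg(fw, fx$features[[1]], observed = -pr$predicted)
  expect_equal(unname(anti$r), rep(-1, 8), tolerance = 1e-12)
})

test_that("backward models reconstruct and beat their pre-onset baseline", {
  fx <- fix_truth_noiseless()
  bw <- fit_backward(fx$trials, fx$features)
  bl <- fit_backward(fx$trials, fx$features, baseline = TRUE)
  expect_gt(bw$reconstruction_r, 0.95)
  expect_gt(bw$reconstruction_r, bl$reconstruction_r)
  expect_identical(bw$baseline, FALSE)
  expect_identical(bl$baseline, TRUE)
  expect_identical(range(bl$taus), c(-13L, 0L))  # -100..0 ms at 128 Hz
  # reconstruct_feature reproduces the fitted reconstruction path
  rec <- reconstruct_feature(bw, speechtrack:::trial_matrix(fx$trials[[1]], 1,
                                                            post_only = TRUE))
  fz <- as.numeric(scale(fx$features[[1]]$values))
  expect_gt(cor(rec, fz), 0.9)
})

test_that("degenerate inputs raise informative errors", {
  fx <- fix_truth_noiseless()
  zero_fe <- feature_series(numeric(320), 128, "Env", "s01")
  expect_error(fit_forward(fx$trials[1], list(s01 = zero_fe)), "degenerate feature")
  expect_error(fit_backward(fx$trials[1], list(s01 = zero_fe)), "degenerate feature")
  one_trial <- fx$trials[[1]]
  one_trial$data <- one_trial$data[1:2, , , drop = FALSE]
  expect_error(fit_forward(list(s01 = one_trial), fx$features["s01"]),
               "at least 3 trials")
  expect_error(lag_set(100, 100, 128), "below")
})

test_that("tidiers and plots expose the fitted models", {
  fx <- fix_truth_noiseless()
  fw <- fit_forward(fx$trials, fx$features)
  td <- tidy(fw)
  expect_identical(nrow(td), length(fw$lags) * 8L)
  expect_identical(names(glance(fw)),
                   c("feature", "lambda", "mean_prediction_r", "trials_averaged"))
  expect_s3_class(autoplot(fw), "ggplot")
})
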