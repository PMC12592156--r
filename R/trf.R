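# Ridge-regularized lagged regression between stimulus features and EEG:
# forward (encoding) models predict each channel from the lagged feature,
# backward (decoding) models reconstruct the feature from all channels
# jointly. Models are fitted independently per trial and averaged; the
# regularization parameter is chosen by leave-one-out cross-validation
# across trials, each held-out trial being predicted by the average of
# the remaining trials' weights.

#' Integer lag set for a time-lag window
#'
#' @param t_min_ms,t_max_ms Window edges in milliseconds (forward-model
#'   convention: positive lags mean the EEG follows the feature).
#' @param fs Sampling rate in Hz.
#' @return Integer vector of contiguous sample lags.
#' @export
lag_set <- function(t_min_ms, t_max_ms, fs) {
  if (t_min_ms >= t_max_ms) abort("t_min_ms must be below t_max_ms")
  seq(round(t_min_ms * fs / 1000), round(t_max_ms * fs / 1000))
}

#' Lagged design matrix
#'
#' Expands a series into a `samples x (lags * channels)` design matrix.
#' Column `(channel c, lag tau)` holds the series of channel `c` delayed
#' by `tau` samples (`x[t - tau]`), zero-filled outside the series, so in
#' a forward model a positive lag lets the EEG at time `t` be explained
#' by the feature at `t - tau`. Columns are ordered channel by channel,
#' lags varying fastest.
#'
#' @param x Numeric vector or `samples x channels` matrix.
#' @param lags Integer sample lags (see [lag_set()]).
#' @return Design matrix with `length(lags) * ncol(x)` columns.
#' @export
lag_matrix <- function(x, lags) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (max(abs(lags)) >= n) abort("lag window longer than the series")
  n_ch <- ncol(x)
  n_lag <- length(lags)
  out <- matrix(0, n, n_ch * n_lag)
  for (j in seq_len(n_ch)) {
    for (k in seq_len(n_lag)) {
      l <- lags[k]
      col <- (j - 1L) * n_lag + k
      if (l >= 0) {
        out[(l + 1):n, col] <- x[1:(n - l), j]
      } else {
        out[1:(n + l), col] <- x[(1 - l):n, j]
      }
    }
  }
  out
}

#' Ridge regression with scale-invariant regularization
#'
#' Solves `w = (X'X + lambda * m * I)^-1 X'Y` with `m` the mean diagonal
#' of `X'X`, so that a given `lambda` has the same meaning whatever the
#' scale of the design. The intercept is unpenalized (fitted by
#' centering). When the design has more columns than rows the
#' numerically equivalent kernel (dual) form is used. A singular system
#' at `lambda = 0` falls back to the pseudoinverse with a warning.
#'
#' @param X Design matrix (`n x p`).
#' @param Y Target vector or matrix (`n x q`).
#' @param lambda Nonnegative regularization parameter.
#' @param intercept Fit an unpenalized intercept (default `TRUE`).
#' @return List with `weights` (`p x q`), `bias` (length `q`), `lambda`
#'   and the scaling constant `m`.
#' @export
ridge_solve <- function(X, Y, lambda, intercept = TRUE) {
  if (lambda < 0) abort("lambda must be nonnegative")
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) abort("X and Y must have the same number of rows")
  xm <- if (intercept) colMeans(X) else numeric(ncol(X))
  ym <- if (intercept) colMeans(Y) else numeric(ncol(Y))
  Xc <- sweep(X, 2, xm)
  Yc <- sweep(Y, 2, ym)
  n <- nrow(Xc)
  p <- ncol(Xc)
  m <- mean(colSums(Xc^2))
  if (m == 0) m <- 1
  w <- if (p <= n) {
    A <- crossprod(Xc)
    diag(A) <- diag(A) + lambda * m
    tryCatch(
      solve(A, crossprod(Xc, Yc)),
      error = function(e) {
        warn("singular normal equations; using pseudoinverse")
        sv <- svd(A)
        pos <- sv$d > max(sv$d) * 1e-12
        sv$v[, pos, drop = FALSE] %*%
          (crossprod(sv$u[, pos, drop = FALSE], crossprod(Xc, Yc)) / sv$d[pos])
      }
    )
  } else {
    K <- tcrossprod(Xc)
    diag(K) <- diag(K) + lambda * m
    alpha <- tryCatch(
      solve(K, Yc),
      error = function(e) {
        warn("singular kernel system; using pseudoinverse")
        sv <- svd(K)
        pos <- sv$d > max(sv$d) * 1e-12
        sv$v[, pos, drop = FALSE] %*%
          (crossprod(sv$u[, pos, drop = FALSE], Yc) / sv$d[pos])
      }
    )
    crossprod(Xc, alpha)
  }
  list(weights = w, bias = as.numeric(ym - crossprod(w, xm)),
       lambda = lambda, m = m)
}

default_lambda_grid <- function() 10^seq(-1, 6)

# Normalize (trials, features) input to parallel lists and check alignment.
align_trials_features <- function(trials, features) {
  if (inherits(trials, "trial_set")) trials <- list(trials)
  if (inherits(features, "feature_series")) features <- list(features)
  if (length(trials) != length(features)) {
    abort("need one feature series per trial set")
  }
  if (!is.null(names(trials)) && !is.null(names(features)) &&
      !identical(sort(names(trials)), sort(names(features)))) {
    abort("trial-set and feature-series names do not match")
  }
  if (!is.null(names(trials)) && !is.null(names(features))) {
    features <- features[names(trials)]
  }
  list(trials = trials, features = features)
}

zscore_vec <- function(x, what = "series") {
  s <- sd(x)
  if (s == 0) abort(sprintf("degenerate %s: constant values", what))
  (x - mean(x)) / s
}

zscore_cols <- function(m, what = "channel") {
  s <- apply(m, 2, sd)
  if (any(s == 0)) abort(sprintf("degenerate %s %d: constant values", what, which(s == 0)[1]))
  scale(m, center = TRUE, scale = s)[, , drop = FALSE]
}

# Post-onset feature vector padded/truncated to the trial's length.
fit_feature_vector <- function(fe, n) {
  v <- fe$values
  if (length(v) < n) v <- c(v, numeric(n - length(v)))
  v[seq_len(n)]
}

#' Fit a forward (encoding) temporal response function
#'
#' Estimates the linear kernel mapping one stimulus feature to every EEG
#' channel over a window of time lags. A ridge model is fitted to each
#' trial separately at every candidate `lambda`; each held-out trial is
#' then predicted by the average of the other trials' kernels, and the
#' `lambda` maximizing the mean held-out prediction correlation (over
#' channels and trials) is retained, ties going to the stronger
#' regularization. The reported TRF is the average of the per-trial fits
#' at that `lambda`, and the reported correlations are always
#' cross-validated. Feature and EEG are z-scored per trial before
#' fitting, so weights are in z-units.
#'
#' @param trials A [trial_set()] or (named) list of them, one per sentence.
#' @param features A [feature_series()] or matching list.
#' @param t_min_ms,t_max_ms Lag window in ms (default -100..500).
#' @param lambdas Regularization grid (default `10^(-1..6)`).
#' @return An object of class `forward_trf` with elements `weights`
#'   (`lag x channel`), `lambda`, `prediction_r` (per channel, held out),
#'   `cv` (per-`lambda` scores) and bookkeeping fields.
#' @export
fit_forward <- function(trials, features, t_min_ms = -100, t_max_ms = 500,
                        lambdas = default_lambda_grid()) {
  al <- align_trials_features(trials, features)
  trials <- al$trials
  features <- al$features
  fs <- trials[[1]]$fs
  lags <- lag_set(t_min_ms, t_max_ms, fs)
  p <- length(lags)
  lambdas <- sort(lambdas)

  prep <- vector("list", length(trials))
  total_trials <- 0L
  for (s in seq_along(trials)) {
    ts <- trials[[s]]
    if (!isTRUE(all.equal(ts$fs, fs))) abort("all trial sets must share one sampling rate")
    n_post <- dim(ts$data)[3] - onset_index(ts) + 1L
    fe <- fit_feature_vector(features[[s]], n_post)
    if (sd(fe) == 0) {
      abort(sprintf("degenerate feature (constant) for sentence %s",
                    ts$sentence))
    }
    fz <- zscore_vec(fe)
    X <- lag_matrix(fz, lags)
    Xc <- sweep(X, 2, colMeans(X))
    XtX <- crossprod(Xc)
    nt <- n_trials(ts)
    Ys <- lapply(seq_len(nt), function(i) {
      zscore_cols(trial_matrix(ts, i, post_only = TRUE), what = "channel")
    })
    XtY <- lapply(Ys, function(y) crossprod(Xc, y))
    prep[[s]] <- list(Xc = Xc, XtX = XtX, m = mean(diag(XtX)),
                      Ys = Ys, XtY = XtY, nt = nt)
    total_trials <- total_trials + nt
  }
  if (total_trials < 3) abort("at least 3 trials are required")
  n_ch <- ncol(prep[[1]]$Ys[[1]])

  eval_lambda <- function(lambda, keep_weights = FALSE) {
    W <- vector("list", length(prep))
    Ssum <- matrix(0, p, n_ch)
    for (s in seq_along(prep)) {
      A <- prep[[s]]$XtX
      diag(A) <- diag(A) + lambda * prep[[s]]$m
      R <- chol(A)
      Ws <- lapply(prep[[s]]$XtY, function(b) backsolve(R, backsolve(R, b, transpose = TRUE)))
      W[[s]] <- Ws
      Ssum <- Ssum + Reduce(`+`, Ws)
    }
    r_ch_sum <- numeric(n_ch)
    r_all <- numeric(0)
    for (s in seq_along(prep)) {
      Xc <- prep[[s]]$Xc
      for (i in seq_len(prep[[s]]$nt)) {
        w_avg <- (Ssum - W[[s]][[i]]) / (total_trials - 1)
        pred <- Xc %*% w_avg
        r <- colwise_cor(pred, prep[[s]]$Ys[[i]])
        r_ch_sum <- r_ch_sum + r
        r_all <- c(r_all, mean(r, na.rm = TRUE))
      }
    }
    list(score = mean(r_all), r_channel = r_ch_sum / total_trials,
         weights = if (keep_weights) Ssum / total_trials else NULL)
  }

  scores <- numeric(length(lambdas))
  best <- -Inf
  best_idx <- 1L
  for (k in seq_along(lambdas)) {
    scores[k] <- eval_lambda(lambdas[k])$score
    if (scores[k] >= best) {  # ties resolved toward larger lambda
      best <- scores[k]
      best_idx <- k
    }
  }
  fin <- eval_lambda(lambdas[best_idx], keep_weights = TRUE)
  weights <- fin$weights
  dimnames(weights) <- list(lag_ms = round(lags / fs * 1000, 3),
                            channel = trials[[1]]$channels)
  structure(list(
    feature = features[[1]]$name,
    weights = weights,
    bias = setNames(numeric(n_ch), trials[[1]]$channels),
    lambda = lambdas[best_idx],
    lambda_grid = lambdas,
    lags = lags,
    lags_ms = lags / fs * 1000,
    fs = fs,
    prediction_r = setNames(fin$r_channel, trials[[1]]$channels),
    cv = tibble(lambda = lambdas, score = scores),
    trials_averaged = total_trials,
    channels = trials[[1]]$channels
  ), class = "forward_trf")
}

#' Predict EEG from a forward TRF
#'
#' Applies a fitted forward model to a stimulus feature, returning the
#' predicted multi-channel response (in z-units) and, when the observed
#' response is supplied, the per-channel Pearson correlation between
#' prediction and observation.
#'
#' @param object A `forward_trf`.
#' @param feature A [feature_series()] (or numeric vector at the model's
#'   sampling rate).
#' @param observed Optional observed `samples x channel` matrix.
#' @return List with `predicted` (`samples x channel`) and `r`
#'   (per-channel correlation, `NULL` without `observed`).
#' @export
predict_eeg <- function(object, feature, observed = NULL) {
  stopifnot(inherits(object, "forward_trf"))
  v <- if (inherits(feature, "feature_series")) feature$values else as.numeric(feature)
  n <- if (is.null(observed)) length(v) else nrow(as.matrix(observed))
  v <- fit_feature_vector(list(values = v), n)
  fz <- zscore_vec(v, what = "feature")
  X <- lag_matrix(fz, object$lags)
  Xc <- sweep(X, 2, colMeans(X))
  pred <- Xc %*% object$weights
  pred <- sweep(pred, 2, object$bias, `+`)
  r <- if (!is.null(observed)) {
    setNames(colwise_cor(pred, as.matrix(observed)), object$channels)
  }
  list(predicted = pred, r = r)
}

#' Fit a backward (decoding) model
#'
#' Estimates the linear decoder reconstructing one stimulus feature from
#' lagged multi-channel EEG. With the target window `0..500` ms the
#' feature at time `t` is read from the EEG at `t + tau`; the baseline
#' variant restricts the window to `-100..0` ms (pre-onset EEG), which
#' for a causal response carries no stimulus information and serves as a
#' null reference. Per-trial fitting, leave-one-out cross-validation and
#' `lambda` selection follow [fit_forward()]; the reconstruction score is
#' the held-out Pearson correlation between reconstructed and true
#' feature, averaged over trials.
#'
#' @inheritParams fit_forward
#' @param t_min_ms,t_max_ms Decoder lag window in ms (default 0..500).
#' @param baseline If `TRUE`, use the -100..0 ms baseline window.
#' @return An object of class `backward_model` with `weights`
#'   (`lag x channel`), `lambda`, `reconstruction_r` and bookkeeping.
#' @export
fit_backward <- function(trials, features, t_min_ms = 0, t_max_ms = 500,
                         baseline = FALSE, lambdas = default_lambda_grid()) {
  if (baseline) {
    t_min_ms <- -100
    t_max_ms <- 0
  }
  al <- align_trials_features(trials, features)
  trials <- al$trials
  features <- al$features
  fs <- trials[[1]]$fs
  taus <- lag_set(t_min_ms, t_max_ms, fs)
  design_lags <- -taus  # feature at t is read from EEG at t + tau
  n_ch <- dim(trials[[1]]$data)[2]
  p <- length(taus) * n_ch
  lambdas <- sort(lambdas)
  n_lam <- length(lambdas)

  # Pass 1: per-trial dual-form ridge at every lambda; accumulate the
  # weight sums and keep each trial's own-projection so the held-out
  # reconstruction can be formed in a second pass without storing any
  # per-trial weight vectors. Small designs are cached to avoid
  # rebuilding the lag matrix in pass 2.
  n_all <- sum(vapply(trials, n_trials, integer(1)))
  n_post_1 <- dim(trials[[1]]$data)[3] - onset_index(trials[[1]]) + 1L
  cache_designs <- n_all * n_post_1 * p * 8 < 4e8
  design_cache <- if (cache_designs) vector("list", n_all)
  trial_index <- list()
  fz_list <- list()
  own <- list()
  Ssum <- matrix(0, p, n_lam)
  total_trials <- 0L
  for (s in seq_along(trials)) {
    ts <- trials[[s]]
    n_post <- dim(ts$data)[3] - onset_index(ts) + 1L
    fe <- fit_feature_vector(features[[s]], n_post)
    if (sd(fe) == 0) {
      abort(sprintf("degenerate feature (constant) for sentence %s", ts$sentence))
    }
    fz_list[[s]] <- zscore_vec(fe)
    for (i in seq_len(n_trials(ts))) {
      Z <- zscore_cols(trial_matrix(ts, i, post_only = TRUE), what = "channel")
      X <- lag_matrix(Z, design_lags)
      Xc <- sweep(X, 2, colMeans(X))
      if (cache_designs) design_cache[[total_trials + 1L]] <- Xc
      K <- tcrossprod(Xc)
      m <- sum(diag(K)) / p
      y <- fz_list[[s]]
      A <- matrix(0, nrow(K), n_lam)
      for (k in seq_len(n_lam)) {
        Kl <- K
        diag(Kl) <- diag(Kl) + lambdas[k] * m
        A[, k] <- solve(Kl, y)
      }
      Ssum <- Ssum + crossprod(Xc, A)
      total_trials <- total_trials + 1L
      own[[total_trials]] <- K %*% A
      trial_index[[total_trials]] <- c(s = s, i = i)
    }
  }
  if (total_trials < 3) abort("at least 3 trials are required")

  # Pass 2: held-out reconstruction r per trial and lambda.
  r_mat <- matrix(NA_real_, total_trials, n_lam)
  for (t in seq_len(total_trials)) {
    s <- trial_index[[t]]["s"]
    i <- trial_index[[t]]["i"]
    Xc <- if (cache_designs) design_cache[[t]] else {
      Z <- zscore_cols(trial_matrix(trials[[s]], i, post_only = TRUE), what = "channel")
      X <- lag_matrix(Z, design_lags)
      sweep(X, 2, colMeans(X))
    }
    recon <- (Xc %*% Ssum - own[[t]]) / (total_trials - 1)
    r_mat[t, ] <- colwise_cor(recon, matrix(fz_list[[s]], nrow(recon), n_lam))
  }
  scores <- colMeans(r_mat)
  best_idx <- 1L
  best <- -Inf
  for (k in seq_len(n_lam)) {
    if (scores[k] >= best) {
      best <- scores[k]
      best_idx <- k
    }
  }
  # lag_matrix orders columns channel-major with lags fastest
  weights <- matrix(Ssum[, best_idx] / total_trials, nrow = length(taus), ncol = n_ch)
  dimnames(weights) <- list(lag_ms = round(taus / fs * 1000, 3),
                            channel = trials[[1]]$channels)
  structure(list(
    feature = features[[1]]$name,
    weights = weights,
    bias = 0,
    lambda = lambdas[best_idx],
    lambda_grid = lambdas,
    taus = taus,
    lags_ms = taus / fs * 1000,
    fs = fs,
    baseline = baseline,
    reconstruction_r = scores[best_idx],
    cv = tibble(lambda = lambdas, score = scores),
    trials_averaged = total_trials,
    channels = trials[[1]]$channels
  ), class = "backward_model")
}

#' Reconstruct a stimulus feature from EEG with a fitted decoder
#'
#' @param object A `backward_model`.
#' @param eeg A `samples x channel` matrix (microvolts or z-units; it is
#'   z-scored per channel before decoding).
#' @return Numeric vector: the reconstructed feature in z-units.
#' @export
reconstruct_feature <- function(object, eeg) {
  stopifnot(inherits(object, "backward_model"))
  Z <- zscore_cols(as.matrix(eeg), what = "channel")
  X <- lag_matrix(Z, -object$taus)
  Xc <- sweep(X, 2, colMeans(X))
  as.numeric(Xc %*% as.vector(object$weights))
}

#' @export
print.forward_trf <- function(x, ...) {
  cat(sprintf("<forward_trf> feature %s: %d lags x %d channels, lambda = %g\n",
              x$feature, nrow(x$weights), ncol(x$weights), x$lambda))
  cat(sprintf("  mean held-out prediction r = %.3f over %d trials\n",
              mean(x$prediction_r, na.rm = TRUE), x$trials_averaged))
  invisible(x)
}

#' @export
print.backward_model <- function(x, ...) {
  cat(sprintf("<backward_model%s> feature %s: window %g..%g ms, lambda = %g\n",
              if (x$baseline) " (baseline)" else "", x$feature,
              min(x$lags_ms), max(x$lags_ms), x$lambda))
  cat(sprintf("  held-out reconstruction r = %.3f over %d trials\n",
              x$reconstruction_r, x$trials_averaged))
  invisible(x)
}

#' @export
tidy.forward_trf <- function(x, ...) {
  tibble(
    feature = x$feature,
    lag_ms = rep(x$lags_ms, times = ncol(x$weights)),
    channel = rep(colnames(x$weights), each = nrow(x$weights)),
    weight = as.vector(x$weights)
  )
}

#' @export
glance.forward_trf <- function(x, ...) {
  tibble(feature = x$feature, lambda = x$lambda,
         mean_prediction_r = mean(x$prediction_r, na.rm = TRUE),
         trials_averaged = x$trials_averaged)
}

#' @export
tidy.backward_model <- function(x, ...) {
  tibble(
    feature = x$feature,
    lag_ms = rep(x$lags_ms, times = ncol(x$weights)),
    channel = rep(colnames(x$weights), each = nrow(x$weights)),
    weight = as.vector(x$weights)
  )
}

#' @export
glance.backward_model <- function(x, ...) {
  tibble(feature = x$feature, baseline = x$baseline, lambda = x$lambda,
         reconstruction_r = x$reconstruction_r,
         trials_averaged = x$trials_averaged)
}

#' @export
autoplot.forward_trf <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lag_ms, y = .data$weight,
                                   group = .data$channel)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(x = "lag (ms)", y = "TRF weight (z-units)",
                  title = sprintf("Forward TRF: %s (lambda = %g)",
                                  object$feature, object$lambda)) +
    ggplot2::theme_minimal()
}
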