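# Internal numerical helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, code)
}

# Derive a child seed from a parent seed and a stream label, staying
# inside 32-bit integer range. Cheap string hash (djb2 variant).
child_seed <- function(seed, ...) {
  label <- paste(c(seed, ...), collapse = "/")
  h <- 5381
  for (ch in utf8ToInt(label)) h <- (h * 33 + ch) %% 2147483647
  as.integer(h)
}

# Nearest-sample index (0-based) for a time in seconds, half-up rounding.
# R's round() is banker's rounding; onsets use the half-up convention.
time_to_sample <- function(t_s, fs) as.integer(floor(t_s * fs + 0.5))

round_half_up <- function(x) floor(x + 0.5)

# Analytic signal via the frequency-domain Hilbert construction.
analytic_signal <- function(x) {
  n <- length(x)
  if (n == 0) return(complex(0))
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

# Zero-phase FIR low-pass (symmetric kernel, group delay compensated).
# `wc` is the cutoff as a fraction of Nyquist.
fir_lowpass_zerophase <- function(x, wc, order = NULL) {
  if (is.null(order)) order <- 2L * ceiling(6 / wc)
  if (order %% 2L == 1L) order <- order + 1L
  h <- as.numeric(signal::fir1(order, wc, type = "low"))
  n <- length(x)
  y <- signal::fftfilt(h, c(x, numeric(order)))
  y[(order / 2 + 1):(order / 2 + n)]
}

# Rational-ratio polyphase resampling with a zero-phase anti-alias FIR.
# Output length is ceiling(n * p / q).
resample_series <- function(x, p, q) {
  stopifnot(p >= 1, q >= 1, p == round(p), q == round(q))
  g <- function(a, b) if (b == 0) a else Recall(b, a %% b)
  d <- g(p, q)
  p <- p / d
  q <- q / d
  if (p == 1 && q == 1) return(x)
  up <- if (p > 1) {
    z <- numeric(length(x) * p)
    z[seq(1, length(z), by = p)] <- x * p
    z
  } else {
    x
  }
  y <- fir_lowpass_zerophase(up, 0.9 / max(p, q), order = 2L * ceiling(12 * max(p, q)))
  y[seq(1, length(y), by = q)]
}

# Express a real resampling ratio as small integers p/q, erroring when the
# ratio cannot be represented rationally within tolerance.
rational_ratio <- function(target_fs, fs, max_den = 1000L) {
  r <- target_fs / fs
  best <- NULL
  for (q in seq_len(max_den)) {
    p <- round(r * q)
    if (p >= 1 && abs(p / q - r) < 1e-9) {
      best <- c(p = p, q = q)
      break
    }
  }
  if (is.null(best)) {
    abort(sprintf("resampling ratio %g/%g is not a small rational number", target_fs, fs))
  }
  best
}

# 1/f^alpha ("pink" for alpha = 1) noise, normalized so the expected
# sample power is 1. Spectral amplitudes are shaped deterministically;
# randomness enters only through the Gaussian Fourier coefficients, so the
# realized power of any one trace fluctuates around 1 as real noise would.
pink_noise <- function(n, alpha = 1) {
  stopifnot(n >= 4)
  m <- floor(n / 2)
  f <- seq_len(m) / n
  amp <- f^(-alpha / 2)
  re <- rnorm(m)
  im <- rnorm(m)
  full <- complex(length.out = n)
  if (n %% 2 == 0) {
    # bins 2..m complex, bin m+1 (Nyquist) real, upper half conjugate
    spec <- complex(real = amp[-m] * re[-m], imaginary = amp[-m] * im[-m])
    full[2:m] <- spec
    full[m + 1] <- complex(real = amp[m] * re[m] * sqrt(2), imaginary = 0)
    full[n:(n - m + 2)] <- Conj(spec)
    expected_power <- (4 * sum(amp[-m]^2) + 2 * amp[m]^2) / n^2
  } else {
    spec <- complex(real = amp * re, imaginary = amp * im)
    full[2:(m + 1)] <- spec
    full[n:(n - m + 1)] <- Conj(spec)
    expected_power <- 4 * sum(amp^2) / n^2
  }
  x <- Re(fft(full, inverse = TRUE)) / n
  x / sqrt(expected_power)
}

# Random orthonormal matrix (QR of a Gaussian matrix, sign-fixed).
random_orthonormal <- function(n) {
  qrd <- qr(matrix(rnorm(n * n), n, n))
  q <- qr.Q(qrd)
  q %*% diag(sign(diag(qr.R(qrd))), n)
}

# Column-wise Pearson correlation between two equal-shape matrices.
colwise_cor <- function(a, b) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  num <- colSums(ac * bc)
  den <- sqrt(colSums(ac^2) * colSums(bc^2))
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

# Pearson r that returns NA (not an error) for zero-variance input.
safe_cor <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
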