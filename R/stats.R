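# Group-comparison statistics: mass-univariate pooled-variance t-tests
# with Benjamini-Hochberg FDR correction, longest significant intervals,
# per-channel dominance within an interval, label-permutation tests on
# per-subject scores with Hedges' g, and N1/P2/N2 peak extraction.

#' Mass-univariate two-sample t-test
#'
#' Student's pooled-variance t at every point of two subject-wise maps
#' (`subject x channel x time` arrays, `subject x time` matrices, or
#' plain per-subject vectors), with two-sided p-values on
#' `n_a + n_b - 2` degrees of freedom. Points with zero pooled variance
#' get `t = 0`, `p = 1` with a warning.
#'
#' @param group_a,group_b Arrays whose first dimension indexes subjects;
#'   the remaining dimensions must match between groups.
#' @return An object of class `group_comparison` holding the `t` and `p`
#'   maps and the degrees of freedom; FDR fields are filled by
#'   [fdr_correct()].
#' @export
pointwise_ttest <- function(group_a, group_b) {
  a <- as_subject_matrix(group_a)
  b <- as_subject_matrix(group_b)
  if (!identical(a$shape, b$shape)) abort("group maps have different shapes")
  n_a <- nrow(a$m)
  n_b <- nrow(b$m)
  if (n_a < 2 || n_b < 2) abort("each group needs at least 2 subjects")
  df <- as.integer(n_a + n_b - 2)
  ma <- colMeans(a$m)
  mb <- colMeans(b$m)
  va <- apply(a$m, 2, var)
  vb <- apply(b$m, 2, var)
  sp2 <- ((n_a - 1) * va + (n_b - 1) * vb) / df
  se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
  tv <- (ma - mb) / se
  zero <- !is.finite(tv)
  if (any(zero)) {
    warn(sprintf("%d point(s) with zero pooled variance; p set to 1", sum(zero)))
    tv[zero] <- 0
  }
  pv <- 2 * pt(-abs(tv), df)
  pv[zero] <- 1
  structure(list(
    t = reshape_map(tv, a$shape), p = reshape_map(pv, a$shape),
    q = NULL, mask = NULL, alpha = NULL, intervals = NULL, dominance = NULL,
    df = df, shape = a$shape, n_a = n_a, n_b = n_b
  ), class = "group_comparison")
}

as_subject_matrix <- function(x) {
  if (is.null(dim(x))) {
    list(m = matrix(x, ncol = 1), shape = list(dim = 1L, dimnames = NULL))
  } else {
    d <- dim(x)
    list(m = matrix(x, nrow = d[1]),
         shape = list(dim = d[-1], dimnames = dimnames(x)[-1]))
  }
}

reshape_map <- function(v, shape) {
  if (length(shape$dim) <= 1) return(as.numeric(v))
  array(v, dim = shape$dim, dimnames = shape$dimnames)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up FDR adjustment over a family of p-values (for TRF
#' comparisons the family is all channels and time points jointly; for
#' channel-averaged PRPs it is all time points).
#'
#' @param p Numeric vector, matrix or array of p-values.
#' @param alpha Significance level after correction (default 0.05).
#' @return List with `q` (adjusted p-values, same shape) and `mask`
#'   (logical, `q <= alpha`).
#' @export
fdr_bh <- function(p, alpha = 0.05) {
  q <- p.adjust(as.numeric(p), method = "BH")
  qm <- p
  qm[] <- q
  list(q = qm, mask = qm <= alpha)
}

#' @rdname fdr_bh
#' @param comparison A `group_comparison` from [pointwise_ttest()].
#' @export
fdr_correct <- function(comparison, alpha = 0.05) {
  stopifnot(inherits(comparison, "group_comparison"))
  fc <- fdr_bh(comparison$p, alpha = alpha)
  comparison$q <- fc$q
  comparison$mask <- fc$mask
  comparison$alpha <- alpha
  comparison
}

#' Longest significant intervals of a comparison mask
#'
#' A time point counts as significant when at least one channel survives
#' FDR there. Maximal consecutive runs of significant time points are
#' returned with their extent in milliseconds and the number of distinct
#' channels significant anywhere inside the run, sorted by duration
#' (longest first) and, among equals, by start time.
#'
#' @param mask Logical `channel x time` matrix (or time vector).
#' @param fs Sampling rate of the time axis in Hz.
#' @param time_ms Optional time axis in ms (defaults to samples starting
#'   at 0).
#' @return Tibble with `start_ms`, `end_ms`, `duration_ms`, `n_samples`,
#'   `n_channels`.
#' @export
significant_intervals <- function(mask, fs, time_ms = NULL) {
  m <- if (is.null(dim(mask))) matrix(mask, nrow = 1) else as.matrix(mask)
  n_t <- ncol(m)
  time_ms <- time_ms %||% ((seq_len(n_t) - 1) / fs * 1000)
  sig_t <- colSums(m) >= 1
  r <- rle(sig_t)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  out <- lapply(keep, function(k) {
    idx <- starts[k]:ends[k]
    tibble(
      start_ms = time_ms[starts[k]],
      end_ms = time_ms[starts[k]] + r$lengths[k] / fs * 1000,
      duration_ms = r$lengths[k] / fs * 1000,
      n_samples = r$lengths[k],
      n_channels = sum(rowSums(m[, idx, drop = FALSE]) > 0)
    )
  })
  out <- if (length(out)) bind_rows(out) else {
    tibble(start_ms = numeric(), end_ms = numeric(), duration_ms = numeric(),
           n_samples = integer(), n_channels = integer())
  }
  arrange(out, desc(.data$duration_ms), .data$start_ms)
}

#' Per-channel dominance within an interval
#'
#' For each channel, the mean absolute response over the interval per
#' group; the group with the larger magnitude is marked dominant (ties
#' are flagged). Signed means are stored alongside.
#'
#' @param group_a,group_b `subject x channel x time` arrays.
#' @param interval Time-sample indices (or logical over time) defining
#'   the interval.
#' @param channels Optional channel labels.
#' @param group_names Length-2 labels for the two groups.
#' @return Tibble with per-channel signed means, magnitudes, `dominant`
#'   and `tie`.
#' @export
dominance_map <- function(group_a, group_b, interval,
                          channels = NULL,
                          group_names = c("a", "b")) {
  stopifnot(length(dim(group_a)) == 3, length(dim(group_b)) == 3)
  if (is.logical(interval)) interval <- which(interval)
  sub_a <- group_a[, , interval, drop = FALSE]
  sub_b <- group_b[, , interval, drop = FALSE]
  mean_a <- apply(sub_a, 2, mean)
  mean_b <- apply(sub_b, 2, mean)
  mag_a <- apply(abs(sub_a), 2, mean)
  mag_b <- apply(abs(sub_b), 2, mean)
  channels <- channels %||% sprintf("ch%02d", seq_along(mean_a))
  dominant <- ifelse(mag_a > mag_b, group_names[1],
                     ifelse(mag_b > mag_a, group_names[2], NA_character_))
  tibble(channel = channels,
         mean_a = mean_a, mean_b = mean_b,
         magnitude_a = mag_a, magnitude_b = mag_b,
         dominant = dominant, tie = mag_a == mag_b)
}

#' Label-permutation test on per-subject scores
#'
#' Compares the mean of two groups of per-subject scores (e.g. stimulus
#' reconstruction correlations) against a surrogate distribution built
#' by shuffling the group labels, with the add-one p-value correction
#' `p = (1 + #{|surrogate| >= |observed|}) / (n_iter + 1)`. The
#' small-sample-corrected standardized mean difference (Hedges' g) is
#' reported alongside.
#'
#' @param scores_a,scores_b Numeric per-subject scores.
#' @param n_iter Number of label shuffles (default 5000; below 100
#'   triggers a warning).
#' @param seed Integer seed for the shuffles.
#' @param alternative `"two.sided"` (default) or `"greater"` /
#'   `"less"` for one-sided tests of `mean(a) - mean(b)`.
#' @return An object of class `permutation_result`.
#' @export
permutation_test <- function(scores_a, scores_b, n_iter = 5000, seed = 1L,
                             alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(scores_a) < 2 || length(scores_b) < 2) {
    abort("each group needs at least 2 scores")
  }
  if (n_iter < 100) warn("fewer than 100 permutation iterations; p-values are coarse")
  observed <- mean(scores_a) - mean(scores_b)
  pool <- c(scores_a, scores_b)
  n_a <- length(scores_a)
  surrogate <- with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      idx <- sample(length(pool), n_a)
      mean(pool[idx]) - mean(pool[-idx])
    }, numeric(1))
  })
  p <- switch(alternative,
    two.sided = (1 + sum(abs(surrogate) >= abs(observed))) / (n_iter + 1),
    greater = (1 + sum(surrogate >= observed)) / (n_iter + 1),
    less = (1 + sum(surrogate <= observed)) / (n_iter + 1)
  )
  structure(list(
    observed = observed,
    p = p,
    n_iter = n_iter,
    surrogate_mean = mean(surrogate),
    surrogate_sd = sd(surrogate),
    hedges_g = hedges_g(scores_a, scores_b),
    alternative = alternative,
    n_a = n_a, n_b = length(scores_b)
  ), class = "permutation_result")
}

#' Hedges' g effect size
#'
#' The pooled-SD standardized mean difference with the small-sample
#' correction `1 - 3 / (4 df - 1)`, `df = n_a + n_b - 2`.
#'
#' @param a,b Numeric per-subject values.
#' @return Hedges' g (signed, `mean(a) - mean(b)` in the numerator).
#' @export
hedges_g <- function(a, b) {
  n_a <- length(a)
  n_b <- length(b)
  df <- n_a + n_b - 2
  sp <- sqrt(((n_a - 1) * var(a) + (n_b - 1) * var(b)) / df)
  d <- (mean(a) - mean(b)) / sp
  d * (1 - 3 / (4 * df - 1))
}

#' Extract N1, P2 and N2 peaks from a response trace
#'
#' Finds the most negative point in the N1 window (50-150 ms), the most
#' positive in the P2 window (120-280 ms) and the most negative in the
#' N2 window (220-400 ms) of a channel-averaged TRF or PRP trace. A
#' window containing no sample of the expected polarity yields a peak
#' flagged as missing.
#'
#' @param trace Numeric time course.
#' @param time_ms Time axis of `trace` in ms.
#' @param windows Named list of search windows in ms.
#' @return A tibble of class `peak_set`: `peak`, `amplitude`,
#'   `latency_ms`, `missing`.
#' @export
extract_peaks <- function(trace, time_ms,
                          windows = list(N1 = c(50, 150),
                                         P2 = c(120, 280),
                                         N2 = c(220, 400))) {
  if (length(trace) != length(time_ms)) abort("trace and time axis differ in length")
  rows <- lapply(names(windows), function(nm) {
    w <- windows[[nm]]
    if (w[1] < min(time_ms) || w[2] > max(time_ms)) {
      abort(sprintf("window %s (%g..%g ms) lies outside the trace", nm, w[1], w[2]))
    }
    idx <- which(time_ms >= w[1] & time_ms <= w[2])
    seg <- trace[idx]
    positive <- startsWith(nm, "P")
    cand <- if (positive) seg > 0 else seg < 0
    if (!any(cand)) {
      return(tibble(peak = nm, amplitude = NA_real_, latency_ms = NA_real_,
                    missing = TRUE))
    }
    k <- if (positive) idx[which.max(seg)] else idx[which.min(seg)]
    tibble(peak = nm, amplitude = trace[k], latency_ms = time_ms[k],
           missing = FALSE)
  })
  out <- bind_rows(rows)
  class(out) <- c("peak_set", class(out))
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> df = %d (%d vs %d subjects)\n",
              x$df, x$n_a, x$n_b))
  if (!is.null(x$q)) {
    cat(sprintf("  FDR alpha = %g: %d of %d points significant\n",
                x$alpha, sum(x$mask), length(x$mask)))
  }
  invisible(x)
}

#' @export
tidy.group_comparison <- function(x, ...) {
  tv <- as.numeric(x$t)
  base <- tibble(t = tv, p = as.numeric(x$p))
  if (!is.null(x$q)) {
    base$q <- as.numeric(x$q)
    base$significant <- as.logical(x$mask)
  }
  d <- x$shape$dim
  if (length(d) == 2) {
    base <- dplyr::bind_cols(
      tibble(channel = rep(x$shape$dimnames[[1]] %||% seq_len(d[1]), times = d[2]),
             time_index = rep(seq_len(d[2]), each = d[1])),
      base
    )
  } else {
    base <- dplyr::bind_cols(tibble(time_index = seq_along(tv)), base)
  }
  base
}

#' @export
glance.permutation_result <- function(x, ...) {
  tibble(observed = x$observed, p = x$p, hedges_g = x$hedges_g,
         n_iter = x$n_iter, alternative = x$alternative,
         n_a = x$n_a, n_b = x$n_b)
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> observed diff = %.4f, p = %.4g (%s, %d iter), Hedges' g = %.3f\n",
              x$observed, x$p, x$alternative, x$n_iter, x$hedges_g))
  invisible(x)
}

#' @export
autoplot.group_comparison <- function(object, ...) {
  df <- tidy(object)
  if ("channel" %in% names(df)) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$time_index, y = .data$channel,
                                     fill = .data$t)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_gradient2() +
      ggplot2::labs(x = "time sample", y = "channel", fill = "t") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$time_index, y = .data$t)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "time sample", y = "t") +
      ggplot2::theme_minimal()
  }
}
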