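# End-to-end driver tying generator -> features -> TRF / PRP -> group
# statistics for a simulated two-group cohort. All stage parameters sit
# in one configuration object with the canonical defaults (200 uV
# rejection, -100..500 ms forward lags, 0..500 ms target and -100..0 ms
# baseline decoder windows, lambda grid 10^-1..10^6, 5000 permutation
# iterations, FDR alpha 0.05/0.01).

#' Pipeline configuration
#'
#' Collects every stage's parameters with the canonical defaults. The
#' simulation block is a [sim_config()]; all analysis windows are in ms.
#'
#' @param sim A [sim_config()] describing the cohort.
#' @param language Which bundled inventory the cohort draws on.
#' @param features Features to fit TRFs and decoders for (subset of the
#'   simulated feature set; default `"Env"`).
#' @param forward_window_ms Forward-model lag window (default -100..500).
#' @param backward_window_ms Target decoder window (default 0..500).
#' @param baseline_window_ms Baseline decoder window (default -100..0).
#' @param lambda_grid Ridge grid (default `10^(-1..6)`).
#' @param reject_uv Amplitude rejection threshold in microvolts.
#' @param alpha FDR significance level (0.05 or 0.01).
#' @param n_iter Permutation iterations (default 5000).
#' @param do_prp Also compute phoneme-related potentials and their group
#'   comparison (default `TRUE`).
#' @param seed Master seed (defaults to the simulation seed).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            language = c("english", "korean"),
                            features = "Env",
                            forward_window_ms = c(-100, 500),
                            backward_window_ms = c(0, 500),
                            baseline_window_ms = c(-100, 0),
                            lambda_grid = default_lambda_grid(),
                            reject_uv = 200,
                            alpha = 0.05,
                            n_iter = 5000,
                            do_prp = TRUE,
                            seed = NULL) {
  language <- match.arg(language)
  if (!alpha %in% c(0.05, 0.01)) {
    warn("alpha outside the conventional {0.05, 0.01} levels")
  }
  structure(list(
    sim = sim, language = language, features = features,
    forward_window_ms = forward_window_ms,
    backward_window_ms = backward_window_ms,
    baseline_window_ms = baseline_window_ms,
    lambda_grid = lambda_grid, reject_uv = reject_uv,
    alpha = alpha, n_iter = n_iter, do_prp = do_prp,
    seed = seed %||% sim$seed
  ), class = "pipeline_config")
}

#' A small demonstration configuration
#'
#' A reduced cohort (fewer subjects, sentences, trials and channels than
#' the canonical design) that runs the full chain in seconds, for
#' examples and smoke tests.
#'
#' @param seed Master seed.
#' @return A [pipeline_config()].
#' @export
demo_pipeline_config <- function(seed = 1L) {
  pipeline_config(
    sim = sim_config(n_per_group = 4L, n_sentences = 2L,
                     trials_per_sentence = 5L, n_channels = 8L,
                     noise_snr_db = 0, seed = seed),
    n_iter = 500
  )
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Generates the cohort, fits per-subject forward TRFs and target plus
#' baseline backward models for each requested feature, computes
#' per-subject phoneme-related potentials, and runs the group
#' comparisons: mass-univariate t-tests with FDR on forward weights and
#' on grand-average PRPs (with significant intervals and a dominance map
#' for the longest one), and permutation tests on reconstruction scores.
#' Deterministic given the configuration.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result` with elements `scores`
#'   (per-subject model summaries), `trf_comparison`, `prp_comparison`,
#'   `permutation`, `prp_similarity` and `log`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  cohort <- gen_cohort(config$sim, default_inventory(config$language))
  truth <- cohort$truth
  groups <- unique(cohort$subjects$group)
  if (length(groups) != 2) abort("the pipeline compares exactly two groups")
  for (f in config$features) {
    if (is.null(truth$features[[1]][[f]])) {
      abort(sprintf("feature '%s' is not available in the simulated stimuli", f))
    }
  }
  annotations <- lapply(truth$sentences, `[[`, "annotation")

  score_rows <- list()
  fwd_weights <- list()   # feature -> group -> list of lag x channel
  prp_grand <- list()     # group -> subject x time
  prp_sets <- list()
  for (si in seq_len(nrow(cohort$subjects))) {
    sub <- cohort$subjects$subject[si]
    grp <- cohort$subjects$group[si]
    trials <- cohort_trials(cohort, sub)
    trials <- lapply(trials, reject_amplitude, threshold_uv = config$reject_uv)
    for (f in config$features) {
      feats <- lapply(truth$features, `[[`, f)
      fw <- fit_forward(trials, feats,
                        t_min_ms = config$forward_window_ms[1],
                        t_max_ms = config$forward_window_ms[2],
                        lambdas = config$lambda_grid)
      bw <- fit_backward(trials, feats,
                         t_min_ms = config$backward_window_ms[1],
                         t_max_ms = config$backward_window_ms[2],
                         lambdas = config$lambda_grid)
      bl <- fit_backward(trials, feats, baseline = TRUE,
                         lambdas = config$lambda_grid)
      fwd_weights[[f]][[grp]] <- c(fwd_weights[[f]][[grp]] %||% list(),
                                   list(t(fw$weights)))
      score_rows[[length(score_rows) + 1L]] <- tibble(
        subject = sub, group = grp, feature = f,
        forward_lambda = fw$lambda,
        forward_r = mean(fw$prediction_r, na.rm = TRUE),
        backward_lambda = bw$lambda,
        reconstruction_r = bw$reconstruction_r,
        baseline_r = bl$reconstruction_r
      )
    }
    if (config$do_prp) {
      ztr <- znorm_channels(trials)
      prp <- average_prp(epoch_phonemes(ztr, annotations))
      prp_sets[[sub]] <- prp
      prp_grand[[grp]] <- rbind(prp_grand[[grp]], prp$grand)
    }
  }
  scores <- bind_rows(score_rows)

  trf_comparison <- list()
  for (f in config$features) {
    wa <- fwd_weights[[f]][[groups[1]]]
    wb <- fwd_weights[[f]][[groups[2]]]
    arr_a <- aperm(simplify2array(wa), c(3, 1, 2))  # subject x channel x lag
    arr_b <- aperm(simplify2array(wb), c(3, 1, 2))
    cmp <- fdr_correct(pointwise_ttest(arr_a, arr_b), alpha = config$alpha)
    lag_ms <- lag_set(config$forward_window_ms[1], config$forward_window_ms[2],
                      config$sim$fs_hz) / config$sim$fs_hz * 1000
    iv <- significant_intervals(cmp$mask, config$sim$fs_hz, time_ms = lag_ms)
    dom <- if (nrow(iv)) {
      idx <- which(lag_ms >= iv$start_ms[1] & lag_ms < iv$end_ms[1])
      dominance_map(arr_a, arr_b, idx, group_names = groups)
    }
    trf_comparison[[f]] <- list(comparison = cmp, intervals = iv, dominance = dom,
                                lag_ms = lag_ms)
  }

  permutation <- list()
  for (f in config$features) {
    sc <- scores[scores$feature == f, ]
    permutation[[f]] <- permutation_test(
      sc$reconstruction_r[sc$group == groups[1]],
      sc$reconstruction_r[sc$group == groups[2]],
      n_iter = config$n_iter,
      seed = child_seed(config$seed, "perm", f)
    )
  }

  prp_comparison <- NULL
  prp_sim <- NULL
  if (config$do_prp) {
    cmp <- fdr_correct(pointwise_ttest(prp_grand[[groups[1]]],
                                       prp_grand[[groups[2]]]),
                       alpha = config$alpha)
    time_ms <- prp_sets[[1]]$time_ms
    iv <- significant_intervals(cmp$mask, config$sim$fs_hz, time_ms = time_ms)
    prp_comparison <- list(comparison = cmp, intervals = iv, time_ms = time_ms)
    prp_sim <- safe_cor(colMeans(prp_grand[[groups[1]]]),
                        colMeans(prp_grand[[groups[2]]]))
  }

  structure(list(
    scores = scores,
    trf_comparison = trf_comparison,
    prp_comparison = prp_comparison,
    permutation = permutation,
    prp_similarity = prp_sim,
    log = list(
      seed = config$seed, groups = groups,
      n_subjects = nrow(cohort$subjects),
      lambda_chosen = scores |>
        group_by(.data$feature) |>
        summarise(forward = stats::median(.data$forward_lambda),
                  backward = stats::median(.data$backward_lambda),
                  .groups = "drop"),
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    )
  ), class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d subjects, features: %s\n",
              x$log$n_subjects, paste(unique(x$scores$feature), collapse = ", ")))
  for (f in names(x$permutation)) {
    pr <- x$permutation[[f]]
    cat(sprintf("  %s reconstruction: diff = %.4f, p = %.4g, g = %.3f\n",
                f, pr$observed, pr$p, pr$hedges_g))
  }
  if (!is.null(x$prp_similarity)) {
    cat(sprintf("  PRP grand-average similarity between groups: r = %.3f\n",
                x$prp_similarity))
  }
  invisible(x)
}

#' @export
glance.pipeline_result <- function(x, ...) {
  bind_rows(lapply(names(x$permutation), function(f) {
    g <- glance(x$permutation[[f]])
    g$feature <- f
    g
  }))
}
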