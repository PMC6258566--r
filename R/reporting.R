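# Reporting module: quantile binning of the stimulus axis, posterior-
# predictive fit summaries with group bootstrap bands, and plot methods.

#' Quantile bin edges of a task's stimulus distribution
#'
#' Bin edges such that the category-mixture stimulus density p(s) =
#' (p(s|C=1) + p(s|C=2)) / 2 has equal mass in each bin, so each bin holds
#' roughly the same number of trials. Outer edges are -Inf / Inf.
#'
#' @param task A [task_spec()].
#' @param n_bins Number of bins (>= 2).
#' @return Numeric vector of length `n_bins + 1`.
#' @examples
#' quantile_bins(task_spec("B"), 4)  # interior edges (-q, 0, q)
#' @export
quantile_bins <- function(task, n_bins) {
  stopifnot(inherits(task, "co_task"), n_bins >= 2)
  cdf <- function(s) {
    0.5 * (stats::pnorm(s, task$mu[1], task$sigma_cat[1]) +
             stats::pnorm(s, task$mu[2], task$sigma_cat[2]))
  }
  probs <- seq_len(n_bins - 1) / n_bins
  lim <- max(abs(task$mu)) + 10 * max(task$sigma_cat)
  edges <- vapply(probs, function(p)
    stats::uniroot(function(s) cdf(s) - p, c(-lim, lim),
                   tol = 1e-9)$root, numeric(1))
  c(-Inf, edges, Inf)
}

# Per-bin summary of one dataset's testing trials for one task:
# mean button press (response), proportion category-2 choices, accuracy,
# mean confidence, per (reliability_level, bin).
binned_stats <- function(d, edges) {
  d$bin <- findInterval(d$orientation_deg, edges, rightmost.closed = TRUE)
  dplyr::summarize(
    d,
    response = mean(.data$response),
    choice2 = mean(.data$chosen_category == 2),
    accuracy = mean(.data$chosen_category == .data$true_category),
    confidence = mean(.data$confidence),
    n = dplyr::n(),
    .by = c("reliability_level", "bin"))
}

#' Posterior-predictive summary of model fits with bootstrap bands
#'
#' For each subject, `n_param_draws` synthetic datasets are simulated from
#' parameter vectors sampled without replacement from the subject's
#' posterior draws, replaying the subject's own stimuli. `n_group_boot`
#' synthetic group datasets are then assembled by picking one synthetic
#' dataset per subject, and the mean per-bin outputs (mean button press,
#' proportion category-2 choices, accuracy, mean confidence) are averaged
#' across subjects within each group dataset. The band is the mean +/- 1
#' s.d. over group datasets (i.e. a group-level s.e.m.); the observed curve
#' is the across-subject mean +/- s.e.m.
#'
#' @param datasets List of trial tibbles, one per subject.
#' @param fits List of `co_fit` objects, parallel to `datasets`.
#' @param n_param_draws Posterior parameter draws (synthetic datasets) per
#'   subject; sampled with replacement (and flagged) if the posterior holds
#'   fewer draws.
#' @param n_group_boot Number of synthetic group datasets.
#' @param n_bins Stimulus quantile bins per task.
#' @param seed Optional seed.
#' @return An object of class `co_fit_summary`: tibble with columns `task`,
#'   `reliability_level`, `bin`, `bin_center`, `stat`, `observed`,
#'   `observed_se`, `model`, `model_sd`.
#' @export
summarize_fit <- function(datasets, fits, n_param_draws = 20,
                          n_group_boot = 1000, n_bins = 6, seed = NULL) {
  if (inherits(datasets, "co_dataset")) datasets <- list(datasets)
  if (inherits(fits, "co_fit")) fits <- list(fits)
  stopifnot(length(datasets) == length(fits), length(fits) >= 1)
  if (!is.null(seed)) set.seed(seed)
  n_subj <- length(datasets)
  model <- fits[[1]]$model
  tasks <- attr(datasets[[1]], "tasks") %||% default_tasks()
  tasks <- tasks[intersect(names(tasks), scope_tasks(model))]
  edges <- lapply(tasks, quantile_bins, n_bins = n_bins)
  flags <- character(0)

  stats_of <- function(d) {
    d <- dplyr::filter(d, .data$phase == "testing",
                       .data$task %in% names(tasks))
    dplyr::bind_rows(lapply(names(tasks), function(tk) {
      dd <- dplyr::filter(d, .data$task == tk)
      cbind(task = tk, binned_stats(dd, edges[[tk]]))
    }))
  }

  obs <- dplyr::bind_rows(lapply(seq_len(n_subj), function(i)
    cbind(subject = i, stats_of(datasets[[i]]))))
  statcols <- c("response", "choice2", "accuracy", "confidence")
  obs_l <- tidyr::pivot_longer(obs, dplyr::all_of(statcols),
                               names_to = "stat", values_to = "value")
  obs_sum <- dplyr::summarize(
    obs_l, observed = mean(.data$value),
    observed_se = stats::sd(.data$value) / sqrt(dplyr::n()),
    .by = c("task", "reliability_level", "bin", "stat"))

  # per-subject x per-draw binned stats of synthetic datasets
  synth <- vector("list", n_subj)
  for (i in seq_len(n_subj)) {
    dr <- dplyr::select(fits[[i]]$draws, -dplyr::any_of(c("chain", "draw",
                                                          "lp")))
    replace <- nrow(dr) < n_param_draws
    if (replace) flags <- c(flags, sprintf(
      "subject %d: fewer posterior draws (%d) than n_param_draws; sampled with replacement",
      i, nrow(dr)))
    idx <- sample.int(nrow(dr), n_param_draws, replace = replace)
    synth[[i]] <- lapply(idx, function(u) {
      th <- unlist(dr[u, ])
      sim <- simulate_responses(datasets[[i]], model, th)
      tidyr::pivot_longer(stats_of(sim), dplyr::all_of(statcols),
                          names_to = "stat", values_to = "value")
    })
  }
  # group bootstrap: one synthetic dataset per subject per replicate
  boot_means <- vector("list", n_group_boot)
  for (bz in seq_len(n_group_boot)) {
    pick <- dplyr::bind_rows(lapply(seq_len(n_subj), function(i)
      synth[[i]][[sample.int(n_param_draws, 1)]]))
    boot_means[[bz]] <- dplyr::summarize(
      pick, value = mean(.data$value), boot = bz,
      .by = c("task", "reliability_level", "bin", "stat"))
  }
  band <- dplyr::summarize(
    dplyr::bind_rows(boot_means),
    model = mean(.data$value),
    model_sd = if (dplyr::n() > 1) stats::sd(.data$value) else NA_real_,
    .by = c("task", "reliability_level", "bin", "stat"))

  centers <- dplyr::bind_rows(lapply(names(tasks), function(tk) {
    e <- edges[[tk]]
    mid <- vapply(seq_len(length(e) - 1), function(j) {
      lo <- if (is.finite(e[j])) e[j] else e[j + 1] - 2
      hi <- if (is.finite(e[j + 1])) e[j + 1] else e[j] + 2
      (lo + hi) / 2
    }, numeric(1))
    tibble::tibble(task = tk, bin = seq_along(mid), bin_center = mid)
  }))
  out <- dplyr::left_join(obs_sum, band,
                          by = c("task", "reliability_level", "bin", "stat"))
  out <- dplyr::left_join(out, centers, by = c("task", "bin"))
  out <- dplyr::relocate(out, "bin_center", .after = "bin")
  attr(out, "model_name") <- model$name
  attr(out, "flags") <- unique(flags)
  class(out) <- c("co_fit_summary", class(out))
  out
}

#' Plot observed psychometric curves
#'
#' Mean response (or choice proportion, accuracy, confidence) against binned
#' stimulus orientation, one line per reliability level, faceted by task.
#'
#' @param data A trial tibble.
#' @param stat One of `"response"`, `"choice2"`, `"accuracy"`,
#'   `"confidence"`.
#' @param n_bins Stimulus quantile bins.
#' @return A ggplot object.
#' @export
plot_psychometric <- function(data, stat = "choice2", n_bins = 6) {
  tasks <- attr(data, "tasks") %||% default_tasks()
  d <- dplyr::filter(data, .data$phase == "testing")
  binned <- dplyr::bind_rows(lapply(intersect(names(tasks), unique(d$task)),
                                    function(tk) {
    dd <- dplyr::filter(d, .data$task == tk)
    e <- quantile_bins(tasks[[tk]], n_bins)
    b <- binned_stats(dd, e)
    b$bin_center <- vapply(b$bin, function(j) {
      lo <- if (is.finite(e[j])) e[j] else e[j + 1] - 2
      hi <- if (is.finite(e[j + 1])) e[j + 1] else e[j] + 2
      (lo + hi) / 2
    }, numeric(1))
    cbind(task = tk, b)
  }))
  ggplot2::ggplot(binned,
                  ggplot2::aes(x = .data$bin_center, y = .data[[stat]],
                               colour = factor(.data$reliability_level))) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~task, scales = "free_x") +
    ggplot2::labs(x = "orientation (deg, binned)", y = stat,
                  colour = "reliability") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.co_fit_summary <- function(object, stat = "choice2", ...) {
  d <- dplyr::filter(object, .data$stat == !!stat)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin_center,
                                  group = .data$reliability_level)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$model - .data$model_sd,
                                      ymax = .data$model + .data$model_sd,
                                      fill = factor(.data$reliability_level)),
                         alpha = 0.3) +
    ggplot2::geom_pointrange(
      ggplot2::aes(y = .data$observed,
                   ymin = .data$observed - .data$observed_se,
                   ymax = .data$observed + .data$observed_se,
                   colour = factor(.data$reliability_level)), size = 0.2) +
    ggplot2::facet_wrap(~task, scales = "free_x") +
    ggplot2::labs(x = "orientation (deg, binned)", y = stat,
                  colour = "reliability", fill = "reliability",
                  title = attr(object, "model_name")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.co_recovery <- function(object, ...) {
  d <- tibble::as_tibble(as.table(object$delta_aic), .name_repair = "minimal")
  names(d) <- c("generator", "fitter", "delta_aic")
  best <- dplyr::slice_min(d, .data$delta_aic, n = 1,
                           by = "generator", with_ties = FALSE)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fitter, y = .data$generator,
                                  fill = .data$delta_aic)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = best, fill = NA, colour = "white",
                       linewidth = 1) +
    ggplot2::scale_fill_gradient(low = "black", high = "grey90") +
    ggplot2::labs(x = "fitted model", y = "generating model",
                  fill = "mean ΔAIC") +
    ggplot2::theme_minimal()
}

#' Plot bootstrapped summed score differences
#'
#' @param boot A [bootstrap_summed_differences()] result.
#' @return A ggplot object (median and 95% CI per model; the reference model
#'   sits at 0).
#' @export
plot_score_differences <- function(boot) {
  ggplot2::ggplot(boot, ggplot2::aes(x = stats::reorder(.data$model,
                                                        .data$median),
                                     y = .data$median)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower,
                                          ymax = .data$upper)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL,
                  y = sprintf("summed score difference vs %s (higher = worse)",
                              attr(boot, "reference_model") %||% "reference")) +
    ggplot2::theme_minimal()
}
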