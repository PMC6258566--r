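# Model-comparison module: point-estimate information criteria, WAIC,
# PSIS-LOO with its Pareto-k diagnostic, bootstrap aggregation of scores
# across datasets, metric rank agreement, and the model-recovery harness.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Point-estimate information criteria
#'
#' AIC = -2 ll + 2 n; BIC = -2 ll + n log t; AICc adds the small-sample
#' correction 2 n (n + 1) / (t - n - 1) to AIC (undefined, returned `NA`,
#' when t <= n + 1). The `elpd_*` columns carry the same quantities on the
#' -1/2 scale used to compare information criteria directly with WAIC and
#' LOO (higher = better).
#'
#' @param loglik Log likelihood at the parameter estimate (for MCMC fits,
#'   the retained sample with the highest log likelihood).
#' @param n_params Number of free parameters.
#' @param n_trials Number of analyzed trials.
#' @return A one-row tibble: `aic`, `bic`, `aicc`, `elpd_aic`, `elpd_bic`,
#'   `elpd_aicc`.
#' @examples
#' information_criteria(-100, 5, 1000)
#' @export
information_criteria <- function(loglik, n_params, n_trials) {
  stopifnot(n_params >= 0, n_trials >= 1)
  aic <- -2 * loglik + 2 * n_params
  bic <- -2 * loglik + n_params * log(n_trials)
  aicc <- if (n_trials > n_params + 1)
    aic + 2 * n_params * (n_params + 1) / (n_trials - n_params - 1)
  else NA_real_
  tibble::tibble(aic = aic, bic = bic, aicc = aicc,
                 elpd_aic = -aic / 2, elpd_bic = -bic / 2,
                 elpd_aicc = -aicc / 2)
}

#' Widely applicable information criterion (WAIC)
#'
#' Computed from the matrix of per-draw per-trial log likelihoods as
#' lppd - p_waic, where lppd sums the log of the mean pointwise likelihood
#' over draws and the effective-parameter penalty p_waic sums the per-trial
#' variances of the log likelihood across draws. Reported on the expected
#' log predictive density scale (comparable to LOO; higher = better).
#'
#' @param pointwise_ll Draws x trials matrix of log likelihoods (>= 2 draws).
#' @return A list with `elpd_waic`, `lppd`, `p_waic`.
#' @export
waic <- function(pointwise_ll) {
  pointwise_ll <- as.matrix(pointwise_ll)
  if (nrow(pointwise_ll) < 2)
    stop("WAIC needs at least 2 posterior draws", call. = FALSE)
  S <- nrow(pointwise_ll)
  lppd_i <- apply(pointwise_ll, 2, logsumexp) - log(S)
  p_i <- apply(pointwise_ll, 2, stats::var)
  list(elpd_waic = sum(lppd_i) - sum(p_i), lppd = sum(lppd_i),
       p_waic = sum(p_i))
}

# Generalized-Pareto fit to exceedances by probability-weighted moments.
# Returns c(k, sigma) for cdf 1 - (1 + k y / sigma)^(-1/k).
gpd_fit_pwm <- function(y) {
  y <- sort(y)
  n <- length(y)
  b0 <- mean(y)
  t1 <- mean(y * (n - seq_len(n)) / (n - 1))
  denom <- b0 - 2 * t1
  if (!is.finite(denom) || denom == 0 || b0 <= 0) return(c(NA_real_, NA_real_))
  k <- 2 - b0 / denom
  sigma <- b0 * (1 - k)
  c(k, sigma)
}

gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log(1 - p))
  sigma / k * ((1 - p)^(-k) - 1)
}

# Pareto-smooth one vector of log importance ratios; returns the smoothed
# log weights (unnormalized) and the tail-shape estimate k-hat.
psis_smooth <- function(lw) {
  S <- length(lw)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  ord <- order(lw)
  if (M < 5 || stats::sd(lw) < 1e-12)
    return(list(lw = lw, khat = -Inf))
  tail_idx <- ord[(S - M + 1):S]
  cutoff <- lw[ord[S - M]]
  exceed <- exp(lw[tail_idx] - cutoff) - 1      # ratios above the threshold
  fit <- gpd_fit_pwm(exceed * exp(cutoff))      # on the raw ratio scale
  khat <- fit[1]
  if (is.finite(khat)) {
    # replace tail by expected order statistics of the fitted tail
    q <- vapply((seq_len(M) - 0.5) / M, gpd_quantile, numeric(1),
                k = fit[1], sigma = fit[2])
    sm <- log(exp(cutoff) + q)
    lw[tail_idx[order(lw[tail_idx])]] <- sm
    # cap smoothed weights at S^(3/4) times the mean weight
    cap <- logsumexp(lw) - log(S) + 0.75 * log(S)
    lw <- pmin(lw, cap)
  } else {
    khat <- Inf
  }
  list(lw = lw, khat = khat)
}

#' PSIS-LOO cross-validated expected log predictive density
#'
#' Approximate leave-one-out cross-validation from posterior draws. For each
#' trial the raw importance ratios 1/p(r_i | theta_u) have their largest 20%
#' (at most 3 sqrt(S)) replaced by the expected order statistics of a
#' generalized Pareto distribution fitted to the tail by probability-weighted
#' moments, with the smoothed weights truncated at S^(3/4) times the mean
#' weight. The tail shape k-hat is the reliability diagnostic: values above
#' 0.7 flag trials whose LOO contribution may be inaccurate.
#'
#' @param pointwise_ll Draws x trials matrix of log likelihoods.
#' @param warn_khat Warn if any k-hat exceeds this (default 0.7).
#' @return A list with `elpd_loo`, `pointwise` (per-trial elpd), `khat`
#'   (per-trial tail shape), `lppd`, `p_loo`.
#' @export
psis_loo <- function(pointwise_ll, warn_khat = 0.7) {
  pointwise_ll <- as.matrix(pointwise_ll)
  S <- nrow(pointwise_ll)
  if (!all(is.finite(pointwise_ll)))
    stop("non-finite pointwise log likelihoods for trials: ",
         paste(utils::head(which(!apply(is.finite(pointwise_ll), 2, all)), 10),
               collapse = ", "), call. = FALSE)
  if (S < 100)
    warning("PSIS-LOO from fewer than 100 draws is unreliable", call. = FALSE)
  n <- ncol(pointwise_ll)
  elpd_i <- numeric(n)
  khat <- numeric(n)
  for (i in seq_len(n)) {
    ll <- pointwise_ll[, i]
    sm <- psis_smooth(-ll)
    lw <- sm$lw
    khat[i] <- sm$khat
    elpd_i[i] <- logsumexp(lw + ll) - logsumexp(lw)
  }
  if (any(khat > warn_khat))
    warning(sum(khat > warn_khat), " trial(s) with Pareto k-hat > ",
            warn_khat, call. = FALSE)
  lppd <- sum(apply(pointwise_ll, 2, logsumexp) - log(S))
  list(elpd_loo = sum(elpd_i), pointwise = elpd_i, khat = khat,
       lppd = lppd, p_loo = lppd - sum(elpd_i))
}

#' Score a fitted model for the comparison table
#'
#' For an MCMC fit ([fit_mcmc()] with `pointwise = TRUE`): AIC/BIC/AICc at
#' the retained draw with the highest log likelihood, plus WAIC and PSIS-LOO
#' from the pointwise matrix. For an MLE fit: information criteria only.
#'
#' @param fit A `co_fit` or `co_mle`.
#' @param dataset Dataset label for the table row.
#' @return One-row tibble with columns `dataset`, `model`, `n_params`,
#'   `n_trials`, the criteria, `waic`, `loo`, `max_khat`.
#' @export
score_fit <- function(fit, dataset = "dataset1") {
  n_params <- if (inherits(fit, "co_mle")) length(fit$theta)
              else nrow(fit$priors)
  if (inherits(fit, "co_mle")) {
    ll <- fit$loglik
    ic <- information_criteria(ll, n_params, fit$n_trials)
    return(tibble::tibble(dataset = dataset, model = fit$model$name,
                          n_params = n_params, n_trials = fit$n_trials,
                          loglik_hat = ll, ic,
                          waic = NA_real_, loo = NA_real_,
                          max_khat = NA_real_))
  }
  stopifnot(inherits(fit, "co_fit"))
  if (is.null(fit$pointwise))
    stop("fit has no pointwise log-likelihood matrix; rerun fit_mcmc with ",
         "pointwise = TRUE", call. = FALSE)
  ll_draws <- rowSums(fit$pointwise)
  ll <- max(ll_draws)
  ic <- information_criteria(ll, n_params, fit$n_trials)
  w <- waic(fit$pointwise)
  l <- psis_loo(fit$pointwise)
  tibble::tibble(dataset = dataset, model = fit$model$name,
                 n_params = n_params, n_trials = fit$n_trials,
                 loglik_hat = ll, ic, waic = w$elpd_waic, loo = l$elpd_loo,
                 max_khat = max(l$khat))
}

#' Build a comparison table from fits
#'
#' @param fits Nested list: `fits[[dataset]][[model]]` of `co_fit` / `co_mle`
#'   objects (names are used as labels).
#' @return A tibble, one row per (dataset, model).
#' @export
comparison_table <- function(fits) {
  rows <- list()
  for (ds in names(fits))
    for (mn in names(fits[[ds]]))
      rows[[length(rows) + 1]] <- score_fit(fits[[ds]][[mn]], dataset = ds)
  out <- dplyr::bind_rows(rows)
  class(out) <- c("co_comparison", class(out))
  out
}

#' Bootstrap summed score differences across datasets
#'
#' Converts each dataset's scores to differences from a reference model
#' (higher difference = worse fit than the reference), then bootstraps the
#' datasets: resample datasets with replacement `n_boot` times, sum the
#' differences per resample, and report the median and central 95% interval
#' of the bootstrapped sums per model.
#'
#' @param score_table Tibble with columns `dataset`, `model` and the metric.
#' @param metric Column name of the score (elpd scale, higher = better).
#' @param reference_model Reference model name; defaults to the model with
#'   the best (highest) mean score.
#' @param n_boot Number of bootstrap resamples.
#' @return A tibble: `model`, `median`, `lower`, `upper` (of summed
#'   reference-minus-model differences; 0 for the reference itself).
#' @export
bootstrap_summed_differences <- function(score_table, metric = "loo",
                                         reference_model = NULL,
                                         n_boot = 10000) {
  stopifnot(metric %in% names(score_table))
  wide <- tidyr::pivot_wider(
    dplyr::select(score_table, dplyr::all_of(c("dataset", "model", metric))),
    names_from = "model", values_from = dplyr::all_of(metric))
  models <- setdiff(names(wide), "dataset")
  if (anyNA(wide[models]))
    stop("missing scores for some (dataset, model) pairs: ",
         paste(wide$dataset[!stats::complete.cases(wide[models])],
               collapse = ", "), call. = FALSE)
  if (is.null(reference_model))
    reference_model <- models[which.max(colMeans(as.matrix(wide[models])))]
  stopifnot(reference_model %in% models)
  diffs <- as.matrix(wide[models])
  diffs <- wide[[reference_model]] - diffs        # higher = worse
  n <- nrow(diffs)
  out <- lapply(models, function(mn) {
    sums <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      sum(diffs[idx, mn])
    }, numeric(1))
    qs <- stats::quantile(sums, c(0.5, 0.025, 0.975), names = FALSE)
    tibble::tibble(model = mn, median = qs[1], lower = qs[2], upper = qs[3])
  })
  res <- dplyr::bind_rows(out)
  attr(res, "reference_model") <- reference_model
  res
}

#' Rank agreement between comparison metrics
#'
#' Spearman rank correlation between every pair of metrics over the
#' (dataset, model) rows, with information criteria on the -1/2 scale so
#' all metrics agree in direction. Ties get average ranks.
#'
#' @param score_table A [comparison_table()] result (or compatible tibble).
#' @param metrics Metric columns to compare (elpd scale).
#' @return A tibble: `metric1`, `metric2`, `rho`.
#' @export
metric_agreement <- function(score_table,
                             metrics = c("elpd_aic", "elpd_bic", "elpd_aicc",
                                         "waic", "loo")) {
  metrics <- intersect(metrics, names(score_table))
  if (dplyr::n_distinct(score_table$model) < 3)
    stop("metric agreement needs at least 3 models", call. = FALSE)
  pairs <- utils::combn(metrics, 2)
  out <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- score_table[[pairs[1, j]]]
    b <- score_table[[pairs[2, j]]]
    ok <- is.finite(a) & is.finite(b)
    tibble::tibble(metric1 = pairs[1, j], metric2 = pairs[2, j],
                   rho = stats::cor(a[ok], b[ok], method = "spearman"))
  })
  dplyr::bind_rows(out)
}

#' Model-recovery analysis
#'
#' Generates synthetic datasets from each model in the set, fits every model
#' in the set to every dataset by bounded maximum likelihood, scores the
#' fits by AIC, and tabulates (a) the confusion matrix of mean AIC
#' differences from the row-best fitted model and (b) the fraction of
#' datasets on which the generating model had the lowest AIC. A comparison
#' procedure that can tell the models apart puts the white diagonal of the
#' confusion matrix on the generator.
#'
#' @param models Named list of [model_spec()]s (or character vector of
#'   registry names).
#' @param n_datasets_per_model Datasets generated per model.
#' @param structure A [session_structure()] for the synthetic subjects.
#' @param parameter_source `"plausible"` (subject-like generating
#'   parameters; default), `"prior"` (raw prior-box draws), or a function
#'   `(model) -> named theta`.
#' @param seed Integer seed.
#' @param n_restarts,maxit Passed to [fit_mle()].
#' @param cross_polish Iteration budget of the final symmetric polish round
#'   for the nested heuristic families (0 disables it).
#' @param stimulus Stimulus preset for generation.
#' @return An object of class `co_recovery`: list with `mean_aic` and
#'   `delta_aic` (generator x fitter matrices), `selection_rate`, `details`
#'   (per-dataset tibble), `failures`.
#' @export
run_model_recovery <- function(models, n_datasets_per_model = 4,
                               structure = session_structure(),
                               parameter_source = "plausible", seed = 1,
                               n_restarts = 2, maxit = 500,
                               cross_polish = 60, stimulus = "gabor") {
  if (is.character(models)) {
    models <- stats::setNames(lapply(models, model_from_name), models)
  }
  if (is.null(names(models)))
    names(models) <- vapply(models, function(m) m$name, character(1))
  draw_theta <- if (is.function(parameter_source)) parameter_source
  else function(model) draw_params(model, 1, source = parameter_source)[1, ]
  set.seed(seed)
  rows <- list()
  failures <- list()
  for (g in names(models)) {
    gen_model <- models[[g]]
    for (r in seq_len(n_datasets_per_model)) {
      theta <- draw_theta(gen_model)
      ds_seed <- sample.int(.Machine$integer.max, 1)
      data <- generate_dataset(gen_model, theta, structure = structure,
                               stimulus = stimulus, seed = ds_seed,
                               subject_id = sprintf("%s_%02d", g, r),
                               testing_only = TRUE)
      fitted <- list()
      for (f in names(models)) {
        # warm-start heuristic fitters from already-fitted heuristic
        # models on this dataset: Fixed seeds Lin/Quad at zero slopes, and
        # Lin/Quad fits are translated into other boundary laws by least
        # squares over the reliability-level sigmas
        extra <- NULL
        if (models[[f]]$family %in% c("fixed", "lin", "quad") &&
            length(fitted)) {
          cand <- list()
          for (nm in names(fitted)) {
            ex <- remap_heuristic(fitted[[nm]]$theta, models[[nm]],
                                  models[[f]], stimulus)
            if (!is.null(ex)) cand[[nm]] <- ex
          }
          if (length(cand)) extra <- do.call(rbind, cand)
        }
        fit <- tryCatch(
          fit_mle(data, models[[f]], n_restarts = n_restarts, maxit = maxit,
                  extra_starts = extra),
          error = function(e) e)
        if (inherits(fit, "error")) {
          failures[[length(failures) + 1]] <-
            list(generator = g, replicate = r, fitter = f,
                 message = conditionMessage(fit))
          next
        }
        fitted[[f]] <- fit
      }
      # cross-polish round: the heuristic families are nested (their AIC
      # margins are a handful of units), so each gets one extra polish from
      # every other heuristic fit's remapped parameters, equalizing the
      # optimization effort regardless of fitting order
      heur <- names(fitted)[vapply(names(fitted), function(nm)
        models[[nm]]$family %in% c("fixed", "lin", "quad"), logical(1))]
      if (cross_polish > 0 && length(heur) > 1) {
        for (f in heur) {
          cand <- list(own = fitted[[f]]$theta)
          for (nm in setdiff(heur, f)) {
            ex <- remap_heuristic(fitted[[nm]]$theta, models[[nm]],
                                  models[[f]], stimulus)
            if (!is.null(ex)) cand[[nm]] <- ex
          }
          refit <- tryCatch(
            fit_mle(data, models[[f]], n_restarts = 1, n_screen = 1,
                    maxit = cross_polish,
                    extra_starts = do.call(rbind, cand)),
            error = function(e) NULL)
          if (!is.null(refit) && refit$loglik > fitted[[f]]$loglik)
            fitted[[f]] <- refit
        }
      }
      for (f in names(fitted)) {
        fit <- fitted[[f]]
        ic <- information_criteria(fit$loglik, length(fit$theta),
                                   fit$n_trials)
        rows[[length(rows) + 1]] <- tibble::tibble(
          generator = g, replicate = r, fitter = f,
          loglik = fit$loglik, n_params = length(fit$theta), aic = ic$aic)
      }
    }
  }
  details <- dplyr::bind_rows(rows)
  # datasets with any failed fit are dropped from the aggregate scores
  complete <- dplyr::filter(
    dplyr::add_count(details, .data$generator, .data$replicate),
    .data$n == length(models))
  mean_aic <- tapply(complete$aic, list(complete$generator, complete$fitter),
                     mean)
  mean_aic <- mean_aic[names(models), names(models), drop = FALSE]
  delta <- sweep(mean_aic, 1, apply(mean_aic, 1, min), "-")
  win <- dplyr::summarize(
    complete, winner = .data$fitter[which.min(.data$aic)],
    .by = c("generator", "replicate"))
  structure(list(mean_aic = mean_aic, delta_aic = delta,
                 selection_rate = mean(win$winner == win$generator),
                 details = details, failures = failures),
            class = "co_recovery")
}

# Translate a fitted Fixed/Lin/Quad parameter vector into a start
# candidate for another heuristic family: noise and lapses carried over,
# each boundary function re-expressed in the target family's sigma law by
# least squares over the six reliability-level sigmas (at s = 0).
remap_heuristic <- function(theta, model_from, model_to, stimulus = "gabor") {
  if (!model_from$family %in% c("fixed", "lin", "quad")) return(NULL)
  if (!model_to$family %in% c("fixed", "lin", "quad")) return(NULL)
  if (model_from$family == model_to$family) return(NULL)
  if (model_from$response_mode != model_to$response_mode ||
      model_from$fit_scope != model_to$fit_scope) return(NULL)
  tasks <- default_tasks(stimulus)
  tab_to <- param_table(model_to)
  out <- stats::setNames(numeric(nrow(tab_to)), tab_to$name)
  shared <- intersect(names(theta), tab_to$name)
  out[shared] <- theta[shared]
  dec <- decode_params(model_from, theta, tasks)
  conf <- model_to$response_mode == "choice_confidence"
  idx <- if (conf) 1:7 else 4
  for (tk in switch(model_to$fit_scope, jointAB = c("A", "B"),
                    taskA = "A", taskB = "B")) {
    sig <- sigma_of(dec$noise_infer, tasks[[tk]]$reliability_values, 0)
    f_from <- switch(model_from$family, fixed = 0 * sig, lin = sig,
                     quad = sig^2)
    f_to <- switch(model_to$family, fixed = NULL, lin = sig, quad = sig^2)
    cr <- dec$crit[[tk]]
    pk <- if (tk == "A") "ka_" else "kb_"
    X <- if (is.null(f_to)) cbind(rep(1, length(sig))) else cbind(1, f_to)
    for (j in seq_along(cr$k)) {
      y <- cr$k[j] + (if (is.null(cr$m)) 0 else cr$m[j]) * f_from
      co <- stats::lm.fit(X, y)$coefficients
      out[paste0(pk, idx[j])] <- co[1]
      if (!is.null(f_to))
        out[paste0(sub("k", "m", pk), idx[j])] <- co[2]
    }
  }
  out
}

#' @export
print.co_recovery <- function(x, ...) {
  cat("<co_recovery> mean delta-AIC (generator rows, fitter columns):\n")
  print(round(x$delta_aic, 1))
  cat(sprintf("correct-selection rate: %.3f (%d fit failures)\n",
              x$selection_rate, length(x$failures)))
  invisible(x)
}

#' Export a recovery confusion matrix as CSV
#'
#' Generators as rows, fitters as columns, cells the mean AIC difference
#' from the row-best fitter, plus a flag column naming the row minimum.
#'
#' @param recovery A [run_model_recovery()] result.
#' @param path Output CSV path.
#' @export
export_recovery <- function(recovery, path) {
  m <- as.data.frame(recovery$delta_aic)
  m$best_fitter <- colnames(recovery$delta_aic)[apply(recovery$delta_aic, 1,
                                                      which.min)]
  utils::write.csv(cbind(generator = rownames(m), m), path,
                   row.names = FALSE)
  invisible(path)
}
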