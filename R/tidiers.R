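# broom-style tidiers for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a slice-sampling MCMC fit
#'
#' One row per parameter: posterior mean, s.d., central 95% interval
#' (sampling scale), plus split R-hat and bulk effective sample size.
#'
#' @param x A `co_fit`.
#' @param natural Report s.d.-like (log-sampled) parameters on their natural
#'   scale by exponentiating the draws first.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.co_fit <- function(x, natural = FALSE, ...) {
  pars <- x$priors$name
  draws <- as.matrix(x$draws[pars])
  if (natural) {
    lg <- x$priors$scale == "log"
    draws[, lg] <- exp(draws[, lg])
  }
  tibble::tibble(
    term = pars,
    estimate = colMeans(draws),
    std.error = apply(draws, 2, stats::sd),
    conf.low = apply(draws, 2, stats::quantile, 0.025),
    conf.high = apply(draws, 2, stats::quantile, 0.975),
    rhat = x$diagnostics$rhat,
    ess = x$diagnostics$ess)
}

#' @rdname tidy.co_fit
#' @export
glance.co_fit <- function(x, ...) {
  tibble::tibble(model = x$model$name, n_params = nrow(x$priors),
                 n_trials = x$n_trials, n_draws = nrow(x$draws),
                 n_chains = x$config$n_chains, max_lp = max(x$draws$lp),
                 max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
                 min_ess = min(x$diagnostics$ess, na.rm = TRUE),
                 flagged = length(x$flags) > 0)
}

#' Tidy a maximum-likelihood fit
#'
#' @param x A `co_mle`.
#' @param natural Report log-sampled parameters on the natural scale.
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate`.
#' @export
tidy.co_mle <- function(x, natural = FALSE, ...) {
  tab <- param_table(x$model)
  est <- x$theta
  if (natural) est <- natural_params(est, tab)
  tibble::tibble(term = tab$name, block = tab$block, estimate = unname(est))
}

#' @rdname tidy.co_mle
#' @export
glance.co_mle <- function(x, ...) {
  ic <- information_criteria(x$loglik, length(x$theta), x$n_trials)
  tibble::tibble(model = x$model$name, logLik = x$loglik,
                 n_params = length(x$theta), n_trials = x$n_trials,
                 AIC = ic$aic, BIC = ic$bic)
}

#' Tidy a model-recovery result
#'
#' @param x A `co_recovery`.
#' @param ... Unused.
#' @return A tibble with one row per (generator, fitter) cell: mean AIC,
#'   mean AIC difference from the row-best fitter, and whether the cell is
#'   the row minimum.
#' @export
tidy.co_recovery <- function(x, ...) {
  d <- tibble::as_tibble(as.table(x$mean_aic), .name_repair = "minimal")
  names(d) <- c("generator", "fitter", "mean_aic")
  dd <- tibble::as_tibble(as.table(x$delta_aic), .name_repair = "minimal")
  d$delta_aic <- dd[[3]]
  dplyr::mutate(d, row_best = .data$delta_aic == min(.data$delta_aic),
                .by = "generator")
}
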