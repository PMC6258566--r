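# Inference module: univariate slice sampling over parameter coordinates,
# the MCMC fitting harness with chain post-processing, convergence
# diagnostics, and a bounded maximum-likelihood mode for the recovery
# harness.

#' Univariate stepping-out slice sampler
#'
#' Coordinate-wise slice sampling: for each coordinate in turn, a slice
#' level is drawn under the log target, the initial interval of width
#' `widths[i]` is expanded by stepping out (capped at `max_steps` expansions
#' per side), and the new value is drawn by shrinkage. The chain leaves the
#' target distribution invariant; no tuning beyond the initial widths is
#' required.
#'
#' @param log_target Function: numeric vector -> log density (up to a
#'   constant; `-Inf` allowed outside the support).
#' @param init Numeric start vector; `log_target(init)` must be finite.
#' @param widths Positive initial interval width per coordinate.
#' @param n Number of sweeps (each updates every coordinate once).
#' @param lower,upper Optional box bounds; the sampler never proposes
#'   outside them.
#' @param max_steps Cap on stepping-out expansions per side.
#' @param max_shrink Cap on shrinkage iterations before erroring (a
#'   safeguard against a mis-specified target).
#' @return A list with `draws` (`n` x d matrix) and `lp` (log target at each
#'   draw).
#' @examples
#' set.seed(1)
#' out <- slice_sample(function(x) -x^2 / 2, init = 0, widths = 1, n = 500)
#' mean(out$draws); var(out$draws)
#' @export
slice_sample <- function(log_target, init, widths, n,
                         lower = rep(-Inf, length(init)),
                         upper = rep(Inf, length(init)),
                         max_steps = 50, max_shrink = 200) {
  d <- length(init)
  stopifnot(length(widths) == d, all(widths > 0),
            length(lower) == d, length(upper) == d)
  x <- as.numeric(init)
  lp <- log_target(x)
  if (!is.finite(lp)) stop("log_target is not finite at init", call. = FALSE)
  draws <- matrix(NA_real_, n, d)
  lps <- numeric(n)
  f1 <- function(xi, i) { x2 <- x; x2[i] <- xi; log_target(x2) }
  for (it in seq_len(n)) {
    for (i in seq_len(d)) {
      y <- lp - stats::rexp(1)
      w <- widths[i]
      L <- x[i] - w * stats::runif(1)
      R <- L + w
      steps <- max_steps
      while (L > lower[i] && steps > 0 && f1(L, i) > y) {
        L <- L - w; steps <- steps - 1
      }
      steps <- max_steps
      while (R < upper[i] && steps > 0 && f1(R, i) > y) {
        R <- R + w; steps <- steps - 1
      }
      L <- max(L, lower[i]); R <- min(R, upper[i])
      ok <- FALSE
      for (tries in seq_len(max_shrink)) {
        x1 <- stats::runif(1, L, R)
        lp1 <- f1(x1, i)
        if (lp1 >= y) { x[i] <- x1; lp <- lp1; ok <- TRUE; break }
        if (x1 < x[i]) L <- x1 else R <- x1
      }
      if (!ok)
        stop("slice shrinkage failed for coordinate ", i, call. = FALSE)
    }
    draws[it, ] <- x
    lps[it] <- lp
  }
  list(draws = draws, lp = lps)
}

#' MCMC chain configuration
#'
#' Defaults are a desk-scale configuration (4 chains of 2000 sweeps); the
#' full-scale analysis in this paradigm used 4-7 chains of 40,000-600,000
#' samples with 6,667 kept per chain. The first `burn_fraction` of each
#' chain is discarded, the remainder is thinned to `keep_per_chain` evenly
#' spaced draws (all post-burn draws if `NULL`), and draws with log
#' posterior more than `lp_drop` below the maximum retained log posterior
#' are removed.
#'
#' @param n_chains Number of chains (run sequentially).
#' @param n_samples Sweeps per chain.
#' @param burn_fraction Fraction discarded from the front of each chain.
#' @param keep_per_chain Target retained draws per chain (`NULL` = all).
#' @param lp_drop Log-posterior filter threshold.
#' @param seed Integer seed for the whole fit.
#' @return A list of class `co_chain_config`.
#' @export
chain_config <- function(n_chains = 4, n_samples = 2000, burn_fraction = 1 / 3,
                         keep_per_chain = NULL, lp_drop = 40, seed = 1) {
  stopifnot(n_chains >= 1, n_samples >= 10,
            burn_fraction > 0, burn_fraction < 1, lp_drop > 0)
  structure(list(n_chains = as.integer(n_chains),
                 n_samples = as.integer(n_samples),
                 burn_fraction = burn_fraction,
                 keep_per_chain = keep_per_chain,
                 lp_drop = lp_drop, seed = as.integer(seed)),
            class = "co_chain_config")
}

# Split R-hat of one parameter: draws x chains matrix, chains split in half.
split_rhat <- function(x) {
  n <- nrow(x)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  sub <- cbind(x[seq_len(half), , drop = FALSE],
               x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub)
  mu <- colMeans(sub)
  s2 <- apply(sub, 2, stats::var)
  W <- mean(s2)
  B <- half * stats::var(mu)
  if (W <= 0) return(if (B <= 0) 1 else Inf)
  sqrt(((half - 1) / half * W + B / half) / W)
}

# Bulk effective sample size via per-(split-)chain autocovariances with
# Geyer's initial monotone positive sequence.
ess_bulk <- function(x) {
  n <- nrow(x)
  if (n < 8) return(NA_real_)
  half <- floor(n / 2)
  sub <- cbind(x[seq_len(half), , drop = FALSE],
               x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub)
  nn <- nrow(sub)
  s2 <- apply(sub, 2, stats::var)
  W <- mean(s2)
  B <- nn * stats::var(colMeans(sub))
  var_hat <- (nn - 1) / nn * W + B / nn
  if (var_hat <= 0) return(NA_real_)
  lag_max <- min(nn - 2, 400)
  acov <- vapply(seq_len(m), function(j) {
    a <- stats::acf(sub[, j], lag.max = lag_max, type = "covariance",
                    plot = FALSE, demean = TRUE)$acf[, 1, 1]
    a
  }, numeric(lag_max + 1))
  rho <- 1 - (W - rowMeans(acov)[-1]) / var_hat
  # paired sums, truncated at the first negative pair, made nonincreasing
  np <- floor(length(rho) / 2)
  if (np < 1) return(m * nn)
  P <- rho[2 * seq_len(np) - 1] + rho[2 * seq_len(np)]
  cut <- which(P < 0)[1]
  if (!is.na(cut)) P <- P[seq_len(cut - 1)]
  if (length(P)) P <- cummin(P)
  tau <- max(1 + 2 * sum(P) + (if (length(rho) %% 2 == 1 && is.na(cut))
    rho[length(rho)] else 0), 1 / 10)
  min(m * nn / tau, m * nn)
}

#' Fit an observer model by slice-sampling MCMC
#'
#' Runs parallel chains of the coordinate-wise slice sampler on the log
#' posterior (uniform sampling-scale priors over the table ranges), from
#' random prior-drawn starting points, then applies the chain-processing
#' rules of [chain_config()]: burn-in, even thinning, and the log-posterior
#' filter. Split R-hat and bulk effective sample size are computed per
#' parameter on the thinned draws (a chain-agreement substitute for visual
#' convergence checks); R-hat above 1.05 sets a warning flag but is not
#' fatal. Per-trial log likelihoods of the retained draws are stored for
#' WAIC / PSIS-LOO.
#'
#' @inheritParams dataset_log_likelihood
#' @param priors A [param_table()], optionally with edited ranges.
#' @param config A [chain_config()].
#' @param pointwise Store the per-draw per-trial log-likelihood matrix.
#' @param start_source `"prior"` (default) or `"plausible"`: distribution of
#'   chain starting points (rejecting points with non-finite posterior).
#' @return An object of class `co_fit`: list with `draws` (tibble: chain,
#'   draw, parameters, lp), `pointwise` (draws x trials matrix or `NULL`),
#'   `diagnostics` (tibble: parameter, rhat, ess), `model`, `priors`,
#'   `config`, `n_trials`, and `flags`.
#' @export
fit_mcmc <- function(data, model, priors = param_table(model),
                     config = chain_config(), tasks = NULL,
                     engine = "auto", pointwise = TRUE,
                     start_source = c("prior", "plausible")) {
  start_source <- match.arg(start_source)
  stopifnot(inherits(model, "co_model"), inherits(config, "co_chain_config"))
  prep <- prepare_trials(data, model, tasks)
  lt <- function(theta) {
    names(theta) <- priors$name
    if (any(theta < priors$lower_s) || any(theta > priors$upper_s))
      return(-Inf)
    sum(pointwise_loglik(prep, model, theta, engine)) -
      sum(log(priors$upper_s - priors$lower_s))
  }
  widths0 <- (priors$upper_s - priors$lower_s) / 10
  set.seed(config$seed)
  burn <- floor(config$n_samples * config$burn_fraction)
  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    init <- NULL
    for (try in seq_len(100)) {
      cand <- draw_params(model, 1, source = start_source, table = priors)[1, ]
      if (is.finite(lt(cand))) { init <- cand; break }
    }
    if (is.null(init))
      stop("could not find a finite-posterior starting point in 100 tries",
           call. = FALSE)
    # burn phase at the initial widths; widths are then tuned once to ~2.5
    # marginal s.d.s of the late burn draws and frozen for the sampling
    # phase (adaptation only during burn-in keeps the sampler valid)
    bp <- slice_sample(lt, init, widths0, max(burn, 2),
                       lower = priors$lower_s, upper = priors$upper_s)
    late <- bp$draws[max(1, floor(nrow(bp$draws) / 2)):nrow(bp$draws), ,
                     drop = FALSE]
    widths <- pmax(2.5 * apply(late, 2, stats::sd), widths0 / 50)
    sp <- slice_sample(lt, bp$draws[nrow(bp$draws), ], widths,
                       config$n_samples - max(burn, 2),
                       lower = priors$lower_s, upper = priors$upper_s)
    chains[[ch]] <- list(draws = rbind(bp$draws, sp$draws),
                         lp = c(bp$lp, sp$lp))
  }
  post_idx <- (burn + 1):config$n_samples
  keep <- config$keep_per_chain
  flags <- character(0)
  if (is.null(keep) || keep >= length(post_idx)) {
    if (!is.null(keep) && keep > length(post_idx))
      flags <- c(flags, "keep_per_chain exceeded post-burn draws; kept all")
    thin_idx <- post_idx
  } else {
    thin_idx <- post_idx[unique(round(seq(1, length(post_idx),
                                          length.out = keep)))]
  }
  draws_by_chain <- lapply(chains, function(cc) cc$draws[thin_idx, , drop = FALSE])
  lp_by_chain <- lapply(chains, function(cc) cc$lp[thin_idx])
  # diagnostics on the thinned, pre-filter draws (equal length per chain)
  diag_tbl <- tibble::tibble(
    parameter = priors$name,
    rhat = vapply(seq_len(nrow(priors)), function(j)
      split_rhat(vapply(draws_by_chain, function(m) m[, j],
                        numeric(length(thin_idx)))), numeric(1)),
    ess = vapply(seq_len(nrow(priors)), function(j)
      ess_bulk(vapply(draws_by_chain, function(m) m[, j],
                      numeric(length(thin_idx)))), numeric(1)))
  if (any(diag_tbl$rhat > 1.05, na.rm = TRUE)) {
    flags <- c(flags, "rhat_above_1.05")
    warning("split R-hat above 1.05 for: ",
            paste(diag_tbl$parameter[which(diag_tbl$rhat > 1.05)],
                  collapse = ", "), call. = FALSE)
  }
  draws <- do.call(rbind, draws_by_chain)
  colnames(draws) <- priors$name
  lp <- unlist(lp_by_chain)
  chain_id <- rep(seq_len(config$n_chains), each = length(thin_idx))
  keep_mask <- lp >= max(lp) - config$lp_drop
  draws <- draws[keep_mask, , drop = FALSE]
  lp <- lp[keep_mask]
  chain_id <- chain_id[keep_mask]
  pw <- NULL
  if (pointwise) {
    pw <- t(vapply(seq_len(nrow(draws)), function(u) {
      th <- draws[u, ]
      names(th) <- priors$name
      pointwise_loglik(prep, model, th, engine)
    }, numeric(nrow(prep$trials))))
  }
  draws_tbl <- tibble::as_tibble(as.data.frame(draws))
  draws_tbl <- dplyr::mutate(draws_tbl, chain = chain_id,
                             draw = seq_len(nrow(draws)), lp = lp,
                             .before = 1)
  structure(list(draws = draws_tbl, pointwise = pw, diagnostics = diag_tbl,
                 model = model, priors = priors, config = config,
                 n_trials = nrow(prep$trials), flags = flags),
            class = "co_fit")
}

#' @export
print.co_fit <- function(x, ...) {
  cat(sprintf("<co_fit %s> %d retained draws (%d chains), %d trials\n",
              x$model$name, nrow(x$draws), x$config$n_chains, x$n_trials))
  cat(sprintf("  max lp %.2f | max split R-hat %.3f\n",
              max(x$draws$lp), max(x$diagnostics$rhat, na.rm = TRUE)))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Fit an observer model by bounded maximum likelihood
#'
#' Best of `n_restarts` bounded quasi-Newton (L-BFGS-B) optimizations of the
#' dataset log likelihood from random starting points, within the prior box.
#' Used by the model-recovery harness, where refitting hundreds of datasets
#' by MCMC would be impractical.
#'
#' @inheritParams fit_mcmc
#' @param bounds A [param_table()] providing the search box.
#' @param n_restarts Number of random restarts.
#' @param start_source Distribution of the random starts.
#' @param n_screen Candidate starts screened; restarts begin from the best
#'   distinct candidates (screening costs one likelihood evaluation per
#'   candidate and makes single restarts far more reliable).
#' @param extra_starts Optional named vector or matrix of additional start
#'   candidates included in the screening (e.g. a fitted nested model's
#'   parameters when warm-starting a supermodel).
#' @param maxit Iteration cap per restart.
#' @return An object of class `co_mle`: list with `theta` (named vector),
#'   `loglik`, `model`, `n_trials`, `restarts` (per-restart summary tibble).
#' @export
fit_mle <- function(data, model, bounds = param_table(model), n_restarts = 2,
                    tasks = NULL, engine = "auto",
                    start_source = c("plausible", "prior"), n_screen = 20,
                    extra_starts = NULL, maxit = 500) {
  start_source <- match.arg(start_source)
  prep <- prepare_trials(data, model, tasks)
  last <- new.env()
  nll <- function(theta) {
    th <- pmin(pmax(theta, bounds$lower_s), bounds$upper_s)
    names(th) <- bounds$name
    ll <- sum(pointwise_loglik(prep, model, th, engine))
    v <- if (!is.finite(ll)) 1e10 else -ll
    last$x <- theta
    last$f <- v
    v
  }
  # forward-difference gradient (p + 1 evaluations instead of 2p), reusing
  # the objective value the optimizer just computed at the same point
  h <- 1e-6 * (bounds$upper_s - bounds$lower_s)
  gr <- function(theta) {
    f0 <- if (!is.null(last$x) && identical(last$x, theta)) last$f
          else nll(theta)
    vapply(seq_along(theta), function(j) {
      hj <- if (theta[j] + h[j] > bounds$upper_s[j]) -h[j] else h[j]
      tj <- theta
      tj[j] <- tj[j] + hj
      (nll(tj) - f0) / hj
    }, numeric(1))
  }
  # screen once; restarts begin from the best distinct candidates
  cands <- draw_params(model, max(n_screen, n_restarts),
                       source = start_source, table = bounds)
  if (!is.null(extra_starts)) {
    if (is.null(dim(extra_starts)))
      extra_starts <- matrix(extra_starts, nrow = 1,
                             dimnames = list(NULL, names(extra_starts)))
    if (!is.null(colnames(extra_starts)))
      extra_starts <- extra_starts[, bounds$name, drop = FALSE]
    lo <- matrix(bounds$lower_s, nrow(extra_starts), nrow(bounds),
                 byrow = TRUE)
    hi <- matrix(bounds$upper_s, nrow(extra_starts), nrow(bounds),
                 byrow = TRUE)
    cands <- rbind(pmin(pmax(extra_starts, lo), hi), cands)
  }
  vals <- apply(cands, 1, nll)
  ord <- order(vals)[seq_len(min(n_restarts, sum(vals < 1e10)))]
  res <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    if (r > length(ord)) {
      res[[r]] <- list(ok = FALSE, msg = "no finite start")
      next
    }
    init <- cands[ord[r], ]
    res[[r]] <- tryCatch({
      o <- stats::optim(init, nll, gr = gr, method = "L-BFGS-B",
                        lower = bounds$lower_s, upper = bounds$upper_s,
                        control = list(maxit = maxit))
      # polish: a fresh quasi-Newton run from the optimum (resets the
      # Hessian approximation; cheap once converged)
      o2 <- stats::optim(o$par, nll, gr = gr, method = "L-BFGS-B",
                         lower = bounds$lower_s, upper = bounds$upper_s,
                         control = list(maxit = maxit))
      if (o2$value < o$value) o <- o2
      list(ok = TRUE, par = o$par, value = o$value,
           convergence = o$convergence)
    }, error = function(e) list(ok = FALSE, msg = conditionMessage(e)))
  }
  ok <- vapply(res, function(r) isTRUE(r$ok), logical(1))
  if (!any(ok))
    stop("all MLE restarts failed: ",
         paste(vapply(res[!ok], function(r) r$msg %||% "?", character(1)),
               collapse = " | "), call. = FALSE)
  vals <- vapply(res, function(r) if (isTRUE(r$ok)) r$value else Inf,
                 numeric(1))
  best <- res[[which.min(vals)]]
  theta <- best$par
  names(theta) <- bounds$name
  restarts <- tibble::tibble(
    restart = seq_len(n_restarts), ok = ok,
    loglik = ifelse(ok, -vals, NA_real_),
    convergence = vapply(res, function(r)
      if (isTRUE(r$ok)) r$convergence else NA_integer_, numeric(1)))
  structure(list(theta = theta, loglik = -best$value, model = model,
                 n_trials = nrow(prep$trials), restarts = restarts),
            class = "co_mle")
}

#' @export
print.co_mle <- function(x, ...) {
  cat(sprintf("<co_mle %s> log lik %.2f at %d parameters (%d trials)\n",
              x$model$name, x$loglik, length(x$theta), x$n_trials))
  invisible(x)
}
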