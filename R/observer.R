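#' Category beliefs of an observer
#'
#' The generative category parameters an observer uses for inference. By
#' default these are the true task parameters with equal priors; models with
#' free category parameters replace them with fitted values.
#'
#' @param task A [task_spec()].
#' @param mu,sigma_cat Believed category means / s.d.s (length 2).
#' @param log_prior_ratio Believed log prior ratio log p(C=1)/p(C=2).
#' @return A list of class `co_beliefs`.
#' @export
category_beliefs <- function(task, mu = task$mu, sigma_cat = task$sigma_cat,
                             log_prior_ratio =
                               log(task$prior_c1 / (1 - task$prior_c1))) {
  structure(list(mu = as.numeric(mu), sigma_cat = as.numeric(sigma_cat),
                 log_prior_ratio = log_prior_ratio),
            class = "co_beliefs")
}

as_beliefs <- function(task, beliefs = NULL) {
  if (is.null(beliefs)) category_beliefs(task) else beliefs
}

# sort each row ascending, preserving matrix shape (apply() drops dims for
# single-column input)
row_sort <- function(m) {
  if (ncol(m) <= 1) return(m)
  t(apply(m, 1, sort))
}

#' Marginal likelihood of a measurement under one category
#'
#' The observer marginalizes the unknown stimulus out of the measurement
#' distribution: the measurement x given category C is Gaussian with the
#' category mean and variance sigma^2 + sigma_C^2.
#'
#' @param x Measurement(s), degrees.
#' @param sigma Measurement s.d. (> 0, recycled).
#' @param mu_c,sigma_c Category mean and s.d.
#' @return Density values.
#' @examples
#' category_likelihood(0, sigma = 0, mu_c = 0, sigma_c = 12)  # 1/(12 sqrt(2 pi))
#' @export
category_likelihood <- function(x, sigma, mu_c, sigma_c) {
  stopifnot(all(sigma >= 0), sigma_c > 0 || all(sigma > 0))
  stats::dnorm(x, mean = mu_c, sd = sqrt(sigma^2 + sigma_c^2))
}

#' Log posterior ratio of category 1 over category 2
#'
#' The Bayesian decision variable d = log p(C=1|x) - log p(C=2|x). In Task A
#' (means +/- mu, equal spread) d is linear in x; in Task B (equal means,
#' different spreads) d is quadratic in x and requires sigma:
#'
#'   d_A = 2 x mu_1 / (sigma^2 + sigma_1^2) + log-prior-ratio
#'   d_B = 1/2 log[(sigma^2 + sigma_2^2) / (sigma^2 + sigma_1^2)]
#'         - x^2 (sigma_2^2 - sigma_1^2) /
#'           (2 (sigma^2 + sigma_1^2)(sigma^2 + sigma_2^2)) + log-prior-ratio
#'
#' @param task A [task_spec()].
#' @param x Measurement(s), degrees.
#' @param sigma Measurement s.d.(s) (recycled against `x`).
#' @param beliefs Optional [category_beliefs()]; defaults to the true task
#'   parameters with the task's prior.
#' @return Numeric vector of log posterior ratios.
#' @examples
#' log_posterior_ratio(task_spec("A"), x = -5, sigma = 5)   # 0.8
#' log_posterior_ratio(task_spec("B"), x = 0, sigma = 4)    # 0.5 log(160/25)
#' @export
log_posterior_ratio <- function(task, x, sigma, beliefs = NULL) {
  b <- as_beliefs(task, beliefs)
  stopifnot(all(sigma >= 0))
  if (task$task_id == "A") {
    2 * x * b$mu[1] / (sigma^2 + b$sigma_cat[1]^2) + b$log_prior_ratio
  } else {
    v1 <- sigma^2 + b$sigma_cat[1]^2
    v2 <- sigma^2 + b$sigma_cat[2]^2
    0.5 * log(v2 / v1) - x^2 * (v2 - v1) / (2 * v1 * v2) + b$log_prior_ratio
  }
}

#' Posterior probability of being correct
#'
#' The posterior probability of category 1 is the logistic of d; the
#' probability of the *chosen* category (the observer's perceived probability
#' of being correct) is the logistic of |d|.
#'
#' @param d Log posterior ratio(s).
#' @param chosen If `TRUE` return the probability of the chosen category
#'   (logistic of |d|) rather than of category 1.
#' @return Probabilities.
#' @examples
#' prob_correct(0)              # 0.5
#' prob_correct(0.8)            # ~0.690
#' @export
prob_correct <- function(d, chosen = FALSE) {
  stats::plogis(if (chosen) abs(d) else d)
}

#' Measurement-space boundaries of the Bayesian observer
#'
#' Inverts the log-posterior-ratio criteria k (on the d scale) into
#' measurement-space boundaries at given sensory uncertainty sigma. Task A
#' has the closed form x = (k - log-prior) (sigma^2 + sigma_1^2) / (2 mu_1),
#' linear in sigma^2. Task B boundaries act on |x| with
#' |x| = sqrt(max(0, (1/2 log[(sigma^2+sigma_2^2)/(sigma^2+sigma_1^2)]
#' + log-prior - k) * 2 (sigma^2+sigma_1^2)(sigma^2+sigma_2^2) /
#' (sigma_2^2 - sigma_1^2))); criteria above the maximum of d collapse to 0
#' (empty region). Boundaries are returned sorted nondecreasing, which for
#' the default leftward category-1 convention means they run from the most
#' confident category-1 region to the most confident category-2 region.
#'
#' @param task A [task_spec()].
#' @param k Numeric vector of d-scale criteria.
#' @param sigma Measurement s.d.(s).
#' @param beliefs Optional [category_beliefs()].
#' @return A `length(sigma)` x `length(k)` matrix of sorted measurement
#'   boundaries (degrees; on |x| for Task B).
#' @examples
#' bayes_boundaries(task_spec("B"), k = 0, sigma = 4)  # ~7.42 deg
#' @export
bayes_boundaries <- function(task, k, sigma, beliefs = NULL) {
  b <- as_beliefs(task, beliefs)
  stopifnot(all(sigma >= 0))
  u <- unique(sigma)
  if (length(u) < length(sigma) / 2) {
    bu <- bayes_boundaries(task, k, u, beliefs)
    return(bu[match(sigma, u), , drop = FALSE])
  }
  if (task$task_id == "A") {
    if (b$mu[1] == 0) stop("Task A inversion requires a nonzero category mean",
                           call. = FALSE)
    bm <- outer(sigma^2 + b$sigma_cat[1]^2, k - b$log_prior_ratio) /
      (2 * b$mu[1])
  } else {
    s1 <- b$sigma_cat[1]; s2 <- b$sigma_cat[2]
    if (s1 == s2)
      stop("Task B boundary inversion undefined when the category s.d.s are equal",
           call. = FALSE)
    v1 <- sigma^2 + s1^2
    v2 <- sigma^2 + s2^2
    dmax <- 0.5 * log(v2 / v1) + b$log_prior_ratio  # d at x = 0
    scale <- 2 * v1 * v2 / (s2^2 - s1^2)
    arg <- sweep(outer(dmax, k, "-"), 1, scale, "*")
    bm <- sqrt(pmax(arg, 0))
  }
  row_sort(bm)
}

#' Grid marginalization of decision noise
#'
#' Models with decision noise add a Gaussian perturbation eta_d ~ N(0,
#' sigma_d^2) to the log posterior ratio on every trial. The response
#' probability is marginalized over a grid of `n_draws` evenly spaced draws of
#' eta_d spanning +/- `span` * sigma_d, weighted by the normal density
#' (normalized to sum to 1). Shifting d by eta is equivalent to shifting the
#' criteria to k - eta.
#'
#' @param sigma_d Decision-noise s.d. (> 0).
#' @param n_draws Odd number of grid draws (default 101).
#' @param span Half-width of the grid in units of sigma_d (default 5; covers
#'   all but ~6e-7 of the mass).
#' @return A list with numeric vectors `eta` and `weight` (summing to 1).
#' @export
dnoise_grid <- function(sigma_d, n_draws = 101, span = 5) {
  stopifnot(sigma_d > 0, n_draws %% 2 == 1, n_draws >= 3, span > 0)
  eta <- seq(-span * sigma_d, span * sigma_d, length.out = n_draws)
  w <- stats::dnorm(eta, 0, sigma_d)
  list(eta = eta, weight = w / sum(w))
}

# ---- Orientation-estimation observer -------------------------------------

# log of the (unnormalized) mixture prior density p(s|C=1) + p(s|C=2)
log_mixture_prior <- function(s, beliefs) {
  p1 <- stats::dnorm(s, beliefs$mu[1], beliefs$sigma_cat[1])
  p2 <- stats::dnorm(s, beliefs$mu[2], beliefs$sigma_cat[2])
  log(p1 + p2)
}

# MAP estimate profile over a grid of measurements at one sigma, by dense-grid
# maximization with parabolic refinement.
shat_profile <- function(x_grid, sigma, beliefs, s_grid) {
  lmix <- log_mixture_prior(s_grid, beliefs)
  step <- s_grid[2] - s_grid[1]
  vapply(x_grid, function(x) {
    lp <- -(s_grid - x)^2 / (2 * sigma^2) + lmix
    j <- which.max(lp)
    if (j == 1 || j == length(s_grid)) return(s_grid[j])
    # parabolic refinement through the three points around the grid argmax
    y1 <- lp[j - 1]; y2 <- lp[j]; y3 <- lp[j + 1]
    den <- y1 - 2 * y2 + y3
    if (den >= 0) return(s_grid[j])
    s_grid[j] + 0.5 * step * (y1 - y3) / den
  }, numeric(1))
}

#' Maximum a posteriori orientation estimate
#'
#' The orientation-estimation observer treats the mixture of the two category
#' stimulus distributions as a prior over orientation and computes the MAP
#' estimate s_hat = argmax_s N(s; x, sigma^2) (p(s|C=1) + p(s|C=2)), then
#' compares s_hat to a set of orientation criteria. The estimate shrinks the
#' measurement toward the prior modes; as sigma -> 0 it approaches x.
#'
#' @param x Measurement(s), degrees.
#' @param sigma Measurement s.d.(s) (> 0; recycled).
#' @param task A [task_spec()].
#' @param beliefs Optional [category_beliefs()].
#' @param s_range,s_resolution Search grid for the maximization (degrees).
#' @return MAP orientation estimate(s), degrees.
#' @export
map_orientation_estimate <- function(x, sigma, task, beliefs = NULL,
                                     s_range = c(-90, 90),
                                     s_resolution = 0.05) {
  b <- as_beliefs(task, beliefs)
  stopifnot(all(sigma > 0))
  n <- max(length(x), length(sigma))
  x <- rep_len(x, n); sigma <- rep_len(sigma, n)
  s_grid <- seq(s_range[1], s_range[2], by = s_resolution)
  out <- numeric(n)
  for (sg in unique(sigma)) {
    i <- which(sigma == sg)
    out[i] <- shat_profile(x[i], sg, b, s_grid)
  }
  out
}

# Lookup table of s_hat over (x, sigma) and boundary inversion for the
# orientation-estimation observer. Criteria k are on the s_hat scale (|s_hat|
# for Task B). Returns length(sigma) x length(k) sorted measurement
# boundaries, linearly interpolated over the sigma grid.
oe_measurement_boundaries <- function(task, k, sigma, beliefs = NULL,
                                      n_x = 500, n_sigma = 50,
                                      x_range = c(-75, 75)) {
  b <- as_beliefs(task, beliefs)
  stopifnot(all(sigma > 0))
  task_b <- task$task_id == "B"
  x_grid <- if (task_b) seq(0, x_range[2], length.out = n_x)
            else seq(x_range[1], x_range[2], length.out = n_x)
  sr <- range(sigma)
  sig_grid <- if (n_sigma == 1 || sr[1] == sr[2]) sr[1]
              else seq(sr[1], sr[2], length.out = n_sigma)
  s_grid <- seq(-90, 90, by = 0.1)
  # boundary value for each sigma grid row and criterion
  bnd <- matrix(NA_real_, length(sig_grid), length(k))
  for (gi in seq_along(sig_grid)) {
    prof <- shat_profile(x_grid, sig_grid[gi], b, s_grid)
    if (any(diff(prof) < -1e-8))
      warning("non-monotone orientation-estimate profile; ",
              "using nearest-crossing inversion")
    prof_mono <- cummax(prof)
    # genuine discontinuities of the MAP estimate (bimodal-posterior mode
    # switches): criteria inside a jump map to the jump location exactly,
    # giving the zero-width response regions of the converged limit instead
    # of grid-width artifacts
    step <- diff(prof_mono)
    jump_tol <- max(1, 10 * stats::median(step))
    bnd[gi, ] <- vapply(k, function(kk) {
      if (kk <= prof_mono[1]) return(if (task_b) 0 else -Inf)
      if (kk >= prof_mono[length(prof_mono)]) return(Inf)
      j <- findInterval(kk, prof_mono)
      x1 <- x_grid[j]; x2 <- x_grid[j + 1]
      y1 <- prof_mono[j]; y2 <- prof_mono[j + 1]
      if (y2 - y1 > jump_tol) return((x1 + x2) / 2)
      if (y2 > y1) x1 + (kk - y1) / (y2 - y1) * (x2 - x1) else x1
    }, numeric(1))
  }
  # interpolate over sigma per criterion
  out <- matrix(NA_real_, length(sigma), length(k))
  if (length(sig_grid) == 1) {
    out[] <- rep(bnd[1, ], each = length(sigma))
  } else {
    for (j in seq_along(k)) {
      fin <- is.finite(bnd[, j])
      if (!any(fin)) { out[, j] <- bnd[1, j]; next }
      if (all(fin)) {
        out[, j] <- stats::approx(sig_grid, bnd[, j], xout = sigma,
                                  rule = 2)$y
      } else {
        # criterion unreachable at some sigmas: carry the infinite value
        out[, j] <- stats::approx(sig_grid, pmin(pmax(bnd[, j], -1e6), 1e6),
                                  xout = sigma, rule = 2)$y
        out[abs(out[, j]) >= 1e6, j] <- sign(out[abs(out[, j]) >= 1e6, j]) * Inf
      }
    }
  }
  if (task_b) out[out < 0] <- 0
  row_sort(out)
}

#' Moments of the linear neural readout
#'
#' A population of Poisson neurons with Gaussian tuning curves (s.d.
#' sigma_TC, gain g = 1/sigma^2) tiling orientation uniformly is read out by
#' weights proportional to each neuron's preferred orientation (w = a s_pref).
#' The readout z = w . r then has
#'
#'   E(z)   = a g s sqrt(2 pi sigma_TC^2)
#'   Var(z) = a g sqrt(2 pi sigma_TC^2) (sigma_TC^2 + s^2)
#'
#' and is approximately Gaussian at high rates. The observer applies criteria
#' directly to z; the stimulus never enters through a measurement x.
#'
#' @param s Stimulus orientation(s), degrees.
#' @param sigma Measurement-noise s.d. parameterizing the gain g = 1/sigma^2.
#' @param a Weight scale (> 0).
#' @param sigma_tc Tuning-curve s.d. (> 0), degrees.
#' @return A list with numeric vectors `mean` and `var`.
#' @export
linear_neural_moments <- function(s, sigma, a, sigma_tc) {
  stopifnot(a > 0, sigma_tc > 0, all(sigma > 0))
  g <- 1 / sigma^2
  k <- a * g * sqrt(2 * pi * sigma_tc^2)
  list(mean = k * s, var = k * (sigma_tc^2 + s^2))
}

#' Heuristic measurement-space boundaries
#'
#' Fixed: boundaries constant in sigma, b_r = k_r. Lin: b_r = k_r + m_r
#' sigma. Quad: b_r = k_r + m_r sigma^2. Task B boundaries act on |x| and are
#' clipped at 0 from below. Boundaries are sorted nondecreasing per sigma so
#' that crossing boundary functions never produce negative-mass regions.
#'
#' @param family `"fixed"`, `"lin"` or `"quad"`.
#' @param k Criterion intercepts (degrees).
#' @param m Slopes (omit or `NULL` for Fixed).
#' @param sigma Measurement s.d.(s).
#' @param task_id `"A"` (full line) or `"B"` (half line on |x|).
#' @return A `length(sigma)` x `length(k)` matrix of sorted boundaries.
#' @examples
#' heuristic_boundaries("quad", k = 1, m = 2, sigma = 3)  # 19
#' @export
heuristic_boundaries <- function(family = c("fixed", "lin", "quad"), k,
                                 m = NULL, sigma, task_id = "A") {
  family <- match.arg(family)
  u <- unique(sigma)
  if (length(u) < length(sigma) / 2) {
    bu <- heuristic_boundaries(family, k, m, u, task_id)
    return(bu[match(sigma, u), , drop = FALSE])
  }
  if (family == "fixed") {
    if (!is.null(m) && any(m != 0))
      stop("Fixed boundaries take no slopes", call. = FALSE)
    bm <- matrix(k, length(sigma), length(k), byrow = TRUE)
  } else {
    stopifnot(length(m) == length(k))
    sc <- if (family == "lin") sigma else sigma^2
    bm <- outer(sc, m) + matrix(k, length(sigma), length(k), byrow = TRUE)
  }
  if (task_id == "B") bm[bm < 0] <- 0
  row_sort(bm)
}

#' Precision-weighted hybrid decision variable
#'
#' A mixture of the precision of the measurement (Fisher information
#' 1/sigma^2) and the perceived probability of being correct:
#' v = omega / sigma^2 + logistic(|d|). Confidence criteria are applied to v;
#' the category comes from d itself. At omega = 0 this reduces to confidence
#' read out from the posterior probability of the chosen category.
#'
#' @param d Log posterior ratio(s).
#' @param sigma Measurement s.d.(s) (> 0).
#' @param omega Precision weight (>= 0).
#' @return The decision variable v.
#' @export
hybrid_decision_variable <- function(d, sigma, omega) {
  stopifnot(all(sigma > 0), omega >= 0)
  omega / sigma^2 + stats::plogis(abs(d))
}
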