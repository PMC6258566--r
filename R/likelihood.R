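# Likelihood module: per-trial response probabilities, lapse mixture,
# dataset log likelihood and log posterior.

# Gaussian interval masses between consecutive boundaries.
# bnd: n x (nresp - 1) ascending boundary matrix. Task A: regions partition
# the measurement line. Task B: boundaries act on |x| (first edge 0), and
# each region is the union of the two symmetric intervals.
interval_masses <- function(bnd, s, sigma_m, task_id) {
  n <- length(s)
  nresp <- ncol(bnd) + 1L
  if (task_id == "A") {
    edges <- cbind(-Inf, bnd, Inf)
    cum <- stats::pnorm((edges - s) / sigma_m)
    p <- cum[, -1, drop = FALSE] - cum[, -ncol(cum), drop = FALSE]
  } else {
    edges <- cbind(0, bnd, Inf)
    up <- stats::pnorm((edges - s) / sigma_m)
    lo <- stats::pnorm((-edges - s) / sigma_m)
    p <- (up[, -1, drop = FALSE] - up[, -ncol(up), drop = FALSE]) +
      (lo[, -ncol(lo), drop = FALSE] - lo[, -1, drop = FALSE])
  }
  pmax(p, 0)
}

# Core (pre-lapse) response probabilities for trials of one task.
# dec: decode_params() output; s, sigma_m, sigma_i: per-trial vectors.
core_probs_task <- function(model, dec, task, s, sigma_m, sigma_i) {
  fam <- model$family
  tk <- task$task_id
  conf <- model$response_mode == "choice_confidence"
  bel <- if (!is.null(dec$beliefs)) dec$beliefs[[tk]] else category_beliefs(task)
  cr <- dec$crit[[tk]]

  if (fam == "linear_neural") {
    mo <- linear_neural_moments(s, sigma_m, dec$extras$a, dec$extras$sigma_tc)
    k <- cr$k
    if (tk == "A") {
      edges <- c(-Inf, sort(k), Inf)
      cum <- vapply(edges, function(e) stats::pnorm(e, mo$mean, sqrt(mo$var)),
                    numeric(length(s)))
      cum <- matrix(cum, nrow = length(s))
      p <- cum[, -1, drop = FALSE] - cum[, -ncol(cum), drop = FALSE]
    } else {
      k <- sort(pmax(k, 0))
      edges <- c(0, k, Inf)
      up <- vapply(edges, function(e) stats::pnorm(e, mo$mean, sqrt(mo$var)),
                   numeric(length(s)))
      lo <- vapply(edges, function(e) stats::pnorm(-e, mo$mean, sqrt(mo$var)),
                   numeric(length(s)))
      up <- matrix(up, nrow = length(s)); lo <- matrix(lo, nrow = length(s))
      p <- (up[, -1, drop = FALSE] - up[, -ncol(up), drop = FALSE]) +
        (lo[, -ncol(lo), drop = FALSE] - lo[, -1, drop = FALSE])
    }
    return(pmax(p, 0))
  }

  boundary_at <- function(criteria, sig) {
    switch(cr$type,
           bayes = bayes_boundaries(task, criteria, sig, bel),
           fixed = , lin = , quad =
             heuristic_boundaries(cr$type, criteria, cr$m, sig, tk),
           orientation_estimation =
             oe_measurement_boundaries(task, criteria, sig, bel),
           stop("unknown criterion type"))
  }

  if (fam == "precision_hybrid") {
    probs <- matrix(NA_real_, length(s), if (conf) 8L else 2L)
    grid <- if (model$d_noise) dnoise_grid(dec$extras$sigma_d) else
      list(eta = 0, weight = 1)
    for (sg in unique(sigma_i)) {
      i <- which(sigma_i == sg)
      probs[i, ] <- hybrid_probs_at(task, cr, dec$extras$omega, sg, s[i],
                                    sigma_m[i], conf, grid, bel)
    }
    return(probs)
  }

  if (cr$type == "bayes" && model$d_noise) {
    grid <- dnoise_grid(dec$extras$sigma_d)
    acc <- 0
    for (j in seq_along(grid$eta)) {
      bnd <- bayes_boundaries(task, cr$k - grid$eta[j], sigma_i, bel)
      acc <- acc + grid$weight[j] * interval_masses(bnd, s, sigma_m, tk)
    }
    return(acc)
  }

  bnd <- boundary_at(cr$k, sigma_i)
  interval_masses(bnd, s, sigma_m, tk)
}

# Exact response probabilities of the precision hybrid at one inference
# sigma. The decision axis u = d (+ decision noise) is cut into segments at
# the category criterion k4 and at +/- the |d|-thresholds implied by the
# v-criteria; each segment carries one (category, confidence) label and
# maps to a measurement interval through the closed-form inversion of d.
# Responses can own a union of segments (confidence is non-monotone in d
# across the category boundary), so masses accumulate per response.
hybrid_probs_at <- function(task, cr, omega, sg, s, sigma_m, conf, grid,
                            bel) {
  nresp <- if (conf) 8L else 2L
  out <- matrix(0, length(s), nresp)
  dj <- numeric(0)
  if (conf) {
    p <- cr$kv - omega / sg^2
    dj <- ifelse(p >= 1, Inf,
                 ifelse(p <= 0.5, 0, stats::qlogis(pmin(p, 1 - 1e-12))))
    dj <- sort(dj)
  }
  finite_dj <- dj[is.finite(dj)]
  bp <- sort(unique(c(-finite_dj, cr$k4, finite_dj)))
  lo <- c(-Inf, bp)
  hi <- c(bp, Inf)
  mid <- ifelse(is.finite(lo) & is.finite(hi), (lo + hi) / 2,
                ifelse(is.finite(hi), hi - 1, lo + 1))
  cat_lab <- ifelse(mid > cr$k4, 1L, 2L)
  resp <- if (conf) {
    lev <- 1L + vapply(mid, function(u) sum(dj < abs(u)), numeric(1))
    choice_to_response(cat_lab, pmin(lev, 4))
  } else cat_lab
  if (task$task_id == "A") {
    fac <- (sg^2 + bel$sigma_cat[1]^2) / (2 * bel$mu[1])
    d_to_x <- function(dv) (dv - bel$log_prior_ratio) * fac
  } else {
    s1 <- bel$sigma_cat[1]; s2 <- bel$sigma_cat[2]
    v1 <- sg^2 + s1^2; v2 <- sg^2 + s2^2
    dmax <- 0.5 * log(v2 / v1) + bel$log_prior_ratio
    scale <- 2 * v1 * v2 / (s2^2 - s1^2)
    d_to_x <- function(dv) sqrt(pmax((dmax - dv) * scale, 0))
  }
  for (j in seq_along(grid$eta)) {
    w <- grid$weight[j]
    dlo <- lo - grid$eta[j]
    dhi <- hi - grid$eta[j]
    for (seg in seq_along(resp)) {
      x1 <- d_to_x(dhi[seg])
      x2 <- d_to_x(dlo[seg])
      a <- min(x1, x2); b <- max(x1, x2)
      mass <- stats::pnorm((b - s) / sigma_m) -
        stats::pnorm((a - s) / sigma_m)
      if (task$task_id == "B")
        mass <- mass + stats::pnorm((-a - s) / sigma_m) -
          stats::pnorm((-b - s) / sigma_m)
      out[, resp[seg]] <- out[, resp[seg]] + w * pmax(mass, 0)
    }
  }
  out
}

#' Core (pre-lapse) response probabilities
#'
#' For each trial, the probability of each of the 8 category + confidence
#' responses (or 2 category responses in choice-only mode) under the model's
#' core decision process: the probability mass of the measurement
#' distribution between consecutive measurement-space boundaries (for the
#' linear neural model, of the readout distribution between its criteria),
#' with decision noise marginalized over its grid where present. Rows sum
#' to 1.
#'
#' @param data A trial tibble (see [generate_dataset()]); only rows whose
#'   task is in the model's scope are used, in order.
#' @param model A [model_spec()].
#' @param theta Named parameter vector on the sampling scale.
#' @param tasks Named list of [task_spec()]s; defaults to the datasets's
#'   `tasks` attribute, or the standard tasks.
#' @return A matrix (trials x responses) of probabilities.
#' @export
core_response_probabilities <- function(data, model, theta, tasks = NULL) {
  prep <- prepare_trials(data, model, tasks)
  dec <- decode_params(model, theta, prep$tasks)
  probs_from_prep(model, dec, prep)
}

probs_from_prep <- function(model, dec, prep) {
  d <- prep$trials
  nresp <- if (model$response_mode == "choice_confidence") 8L else 2L
  probs <- matrix(NA_real_, nrow(d), nresp)
  for (tk in names(prep$tasks)) {
    i <- which(d$task == tk)
    if (!length(i)) next
    sm <- trial_sigma(dec$noise, d[i, ])
    si <- if (identical(dec$noise_infer, dec$noise)) sm
          else trial_sigma(dec$noise_infer, d[i, ])
    probs[i, ] <- core_probs_task(model, dec, prep$tasks[[tk]],
                                  d$orientation_deg[i], sm, si)
  }
  probs
}

trial_sigma <- function(noise, d) {
  rel <- if (noise$mode == "nonparametric") d$reliability_level
         else d$reliability_value
  sigma_of(noise, rel, d$orientation_deg)
}

#' Mix lapse processes into a response distribution
#'
#' Three mutually exclusive lapse events can replace the core response on any
#' trial: a full lapse (probability `lambda_full`; category uniform,
#' confidence drawn from the 4-level distribution interpolating linearly
#' between endpoint weights `lambda_1` and `lambda_4`, renormalized), a
#' confidence lapse (`lambda_conf`; the core category marginal is kept,
#' confidence uniform), and a repeat lapse (`lambda_repeat`; the previous
#' response is repeated). With no previous response the repeat mass is
#' redistributed proportionally over the remaining mixture components. In
#' choice-only mode the lapse parameters are `lambda` (uniform category) and
#' `lambda_repeat`.
#'
#' @param core_probs Probability vector (length 8 or 2) or matrix (trials x
#'   responses) summing to 1 per row.
#' @param lapses Named list of lapse rates.
#' @param previous_response Previous response code(s); `NA` or `NULL` for
#'   none.
#' @return Same shape as `core_probs`.
#' @export
apply_lapses <- function(core_probs, lapses, previous_response = NULL) {
  vec <- is.null(dim(core_probs))
  P <- if (vec) matrix(core_probs, 1) else core_probs
  n <- nrow(P)
  nresp <- ncol(P)
  prev <- rep_len(if (is.null(previous_response)) NA_integer_
                  else as.integer(previous_response), n)
  lr <- lapses$lambda_repeat %||% 0
  if (nresp == 8L) {
    lf <- lapses$lambda_full %||% 0
    lc <- lapses$lambda_conf %||% 0
    w <- conf_lapse_weights(lapses$lambda_1 %||% 0, lapses$lambda_4 %||% 0)
    # responses 1..8 have confidence 4,3,2,1,1,2,3,4
    full <- 0.5 * w[c(4, 3, 2, 1, 1, 2, 3, 4)]
    pcat1 <- rowSums(P[, 1:4, drop = FALSE])
    confl <- cbind(matrix(pcat1 / 4, n, 4), matrix((1 - pcat1) / 4, n, 4))
    out <- (1 - lf - lc - lr) * P +
      lf * matrix(full, n, 8, byrow = TRUE) + lc * confl
  } else {
    lf <- lapses$lambda %||% 0
    out <- (1 - lf - lr) * P + lf / 2
  }
  if (lr > 0) {
    has_prev <- !is.na(prev)
    rep_mat <- matrix(0, n, nresp)
    rep_mat[cbind(which(has_prev), prev[has_prev])] <- 1
    out <- out + lr * rep_mat
    # first trial: renormalize over the remaining components
    if (any(!has_prev)) out[!has_prev, ] <- out[!has_prev, , drop = FALSE] / (1 - lr)
  }
  if (vec) drop(out) else out
}

# Full-lapse confidence weights over levels 1..4: linear interpolation from
# lambda_1 to lambda_4, renormalized (uniform if both endpoints are 0).
conf_lapse_weights <- function(lambda_1, lambda_4) {
  w <- lambda_1 + (0:3) / 3 * (lambda_4 - lambda_1)
  if (sum(w) <= 0) rep(0.25, 4) else w / sum(w)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- Dataset preparation --------------------------------------------------

default_tasks <- function(stimulus = "gabor") {
  list(A = task_spec("A", stimulus), B = task_spec("B", stimulus))
}

# Filter a dataset to the analyzed (testing) trials in the model's scope,
# attach task specs, and compute each trial's previous response (lagged
# within session x task, in block/trial order; training trials are never
# analyzed and never serve as the previous response).
prepare_trials <- function(data, model, tasks = NULL) {
  stopifnot(is.data.frame(data))
  tasks <- tasks %||% attr(data, "tasks") %||%
    default_tasks(attr(data, "stimulus") %||% "gabor")
  d <- dplyr::filter(data, .data$phase == "testing")
  if (!nrow(d)) stop("dataset has no testing trials", call. = FALSE)
  d <- dplyr::arrange(d, .data$session, .data$task, .data$block, .data$trial)
  d <- dplyr::mutate(d, prev_response = dplyr::lag(.data$response),
                     .by = c("session", "task"))
  keep <- scope_tasks(model)
  d <- dplyr::filter(d, .data$task %in% keep)
  if (!nrow(d))
    stop("no testing trials for the model's task scope (",
         paste(keep, collapse = ", "), ")", call. = FALSE)
  if (model$response_mode == "choice_only") {
    d$response <- d$chosen_category
    d <- dplyr::mutate(d, prev_response = dplyr::lag(.data$chosen_category),
                       .by = c("session", "task"))
  }
  tasks <- tasks[intersect(names(tasks), keep)]
  belvec <- function(tk) {
    task <- tasks[[tk]]
    if (is.null(task)) return(c(0, 1, 2, 0))
    b <- category_beliefs(task)
    c(b$mu[1], b$sigma_cat[1], b$sigma_cat[2], b$log_prior_ratio)
  }
  list(trials = d, tasks = tasks,
       # static columns for the compiled path
       task_int = as.integer(d$task == "B") + 1L,
       resp_int = as.integer(d$response),
       prev_int = ifelse(is.na(d$prev_response), 0L,
                         as.integer(d$prev_response)),
       rel = d$reliability_value,
       lvl = as.integer(d$reliability_level),
       sinabs = abs(sin(pi * d$orientation_deg / 90)),
       rel_range = range(tasks[[1]]$reliability_values),
       belA = belvec("A"), belB = belvec("B"))
}

#' Dataset log likelihood
#'
#' The sum over analyzed (testing) trials of the log probability of the
#' observed response under the model: Gaussian interval masses between the
#' model's measurement-space boundaries, mixed with the lapse processes. A
#' compiled fast path is used for the closed-form boundary families
#' (fixed/lin/quad and the Bayesian models without decision noise); the pure
#' R path covers every family and is used otherwise (`engine` forces one).
#'
#' @inheritParams core_response_probabilities
#' @param pointwise Also return the per-trial log likelihood vector.
#' @param engine `"auto"`, `"r"` or `"cpp"`.
#' @return The scalar log likelihood, or (if `pointwise`) a list with
#'   elements `loglik` and `pointwise`. A trial with probability 0 yields
#'   `-Inf` with a diagnostic attribute `zero_trials`.
#' @export
dataset_log_likelihood <- function(data, model, theta, tasks = NULL,
                                   pointwise = FALSE,
                                   engine = c("auto", "r", "cpp")) {
  engine <- match.arg(engine)
  prep <- prepare_trials(data, model, tasks)
  ll <- pointwise_loglik(prep, model, theta, engine)
  total <- sum(ll)
  if (any(ll == -Inf)) {
    attr(total, "zero_trials") <- which(ll == -Inf)
  }
  if (pointwise) list(loglik = total, pointwise = ll) else total
}

use_cpp <- function(model, engine) {
  if (engine == "r") return(FALSE)
  ok <- model$family %in% c("fixed", "lin", "quad", "bayes_ultrastrong",
                            "bayes_strong", "bayes_weak") && !model$d_noise
  if (engine == "cpp" && !ok)
    stop("compiled path only covers the closed-form boundary families",
         call. = FALSE)
  ok
}

pointwise_loglik <- function(prep, model, theta, engine = "auto") {
  if (use_cpp(model, engine)) {
    return(cpp_pointwise(prep, model, theta))
  }
  dec <- decode_params(model, theta, prep$tasks)
  d <- prep$trials
  probs <- probs_from_prep(model, dec, prep)
  mixed <- apply_lapses(probs, dec$lapses, d$prev_response)
  p <- mixed[cbind(seq_len(nrow(d)), as.integer(d$response))]
  log(p)
}

# Positional extraction plan for the compiled path (pure function of the
# model spec; memoized). Positions index into the param_table row order.
fast_plan <- function(model) {
  key <- paste("plan", model$name, model$fit_scope)
  hit <- .co_cache$param_table[[key]]
  if (!is.null(hit)) return(hit)
  tab <- param_table(model)
  nm <- tab$name
  p <- function(x) match(x, nm)
  conf <- model$response_mode == "choice_confidence"
  fam <- model$family
  fam_code <- match(fam, c("fixed", "lin", "quad"))
  fam_code <- if (is.na(fam_code)) 3L else fam_code - 1L
  bayes <- fam_code == 3L
  kidx <- function(tk) {
    pfx <- if (fam == "bayes_ultrastrong") "k_"
           else if (tk == "A") "ka_" else "kb_"
    if (!conf) return(p(paste0(pfx, 4)))
    if (bayes) {
      if (fam == "bayes_weak" && tk == "B") p(paste0(pfx, 1:7))
      else p(paste0(pfx, 1:4))        # symmetric; expanded at eval time
    } else p(paste0(pfx, 1:7))
  }
  midx <- function(tk) {
    if (!fam %in% c("lin", "quad")) return(integer(0))
    pfx <- if (tk == "A") "ma_" else "mb_"
    if (conf) p(paste0(pfx, 1:7)) else p(paste0(pfx, 4))
  }
  noise_pos <- function(prefix = "") {
    if (model$nonparam_sigma) p(paste0(prefix, "sigma_rel_", 1:6))
    else p(paste0(prefix, c("sigma_low", "sigma_high", "beta")))
  }
  plan <- list(
    nm = nm, islog = tab$scale == "log", fam_code = fam_code,
    bayes = bayes, conf = conf,
    sym_A = bayes && conf,
    sym_B = bayes && conf && fam != "bayes_weak",
    noise_mode = if (model$nonparam_sigma) 1L else 0L,
    noise = noise_pos(),
    noise_i = if (model$noise_split) noise_pos("infer_") else integer(0),
    psi = if (model$orientation_dep_noise) p("psi") else NA_integer_,
    psi_i = if (model$noise_split && model$orientation_dep_noise)
      p("infer_psi") else NA_integer_,
    kA = if ("A" %in% scope_tasks(model)) kidx("A") else integer(0),
    kB = if ("B" %in% scope_tasks(model)) kidx("B") else integer(0),
    mA = if ("A" %in% scope_tasks(model)) midx("A") else integer(0),
    mB = if ("B" %in% scope_tasks(model)) midx("B") else integer(0),
    bel = if (model$free_category_params)
      list(sa = p("bel_sigma_a"), sb1 = p("bel_sigma_b1"),
           sb2 = p("bel_sigma_b2"), lpr = p("bel_lpr")) else NULL,
    lapse = if (conf) p(c("lambda_full", "lambda_1", "lambda_4",
                          "lambda_conf", "lambda_repeat"))
            else p(c("lambda", "lambda_repeat")))
  .co_cache$param_table[[key]] <- plan
  plan
}

cpp_pointwise <- function(prep, model, theta) {
  pl <- fast_plan(model)
  if (!is.null(names(theta)) && !identical(names(theta), pl$nm))
    theta <- theta[pl$nm]
  v <- unname(theta)
  v[pl$islog] <- exp(v[pl$islog])
  psi_of <- function(pos) if (is.na(pos)) 0 else v[pos]
  nz <- function(noise_pos, psi_pos) {
    if (pl$noise_mode == 0L)
      c(v[noise_pos], psi_of(psi_pos), prep$rel_range)
    else c(v[noise_pos], psi_of(psi_pos))
  }
  crit <- function(pos, sym) {
    k <- v[pos]
    if (sym && length(k) == 4) symmetric_criteria(k) else k
  }
  belA <- prep$belA
  belB <- prep$belB
  if (!is.null(pl$bel)) {
    lpr <- v[pl$bel$lpr]
    if (!is.na(pl$bel$sa)) belA <- c(belA[1], v[pl$bel$sa], v[pl$bel$sa], lpr)
    if (!is.na(pl$bel$sb1)) belB <- c(0, v[pl$bel$sb1], v[pl$bel$sb2], lpr)
  }
  co_fast_loglik_cpp(
    task = prep$task_int, s = prep$trials$orientation_deg,
    sinabs = prep$sinabs, rel = prep$rel, lvl = prep$lvl,
    resp = prep$resp_int, prev = prep$prev_int, family = pl$fam_code,
    noise_mode = pl$noise_mode,
    nzG = nz(pl$noise, pl$psi),
    nzI = if (length(pl$noise_i)) nz(pl$noise_i, pl$psi_i) else numeric(0),
    kA = if (length(pl$kA)) crit(pl$kA, pl$sym_A) else numeric(0),
    mA = v[pl$mA], kB = if (length(pl$kB)) crit(pl$kB, pl$sym_B)
    else numeric(0),
    mB = v[pl$mB], belA = belA, belB = belB,
    lapse = v[pl$lapse], conf = pl$conf)
}

#' Log posterior of a parameter vector
#'
#' Log likelihood plus the log prior density on the sampling scale: priors
#' are uniform on the sampling scale over each parameter's range (hence
#' log-uniform on the natural scale for s.d.-like parameters), so the log
#' prior is a constant inside the prior box and `-Inf` outside it.
#'
#' @inheritParams dataset_log_likelihood
#' @param priors A [param_table()] (optionally with edited ranges).
#' @return Scalar log posterior.
#' @export
log_posterior <- function(data, model, theta, priors = param_table(model),
                          tasks = NULL, engine = "auto") {
  theta <- theta[priors$name]
  if (any(!is.finite(theta)) ||
      any(theta < priors$lower_s) || any(theta > priors$upper_s))
    return(-Inf)
  lp <- -sum(log(priors$upper_s - priors$lower_s))
  ll <- dataset_log_likelihood(data, model, theta, tasks = tasks,
                               engine = engine)
  as.numeric(ll) + lp
}
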