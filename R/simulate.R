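# Synthetic-experiment module: stimulus draws, full-session dataset
# generation from any observer model, CSV round-trip, and the noiseless
# ideal-observer accuracy of each task.

#' Draw stimulus orientations from a category
#'
#' @param task A [task_spec()].
#' @param category 1 or 2.
#' @param n Number of draws.
#' @return Orientations in degrees, `Normal(mu[category],
#'   sigma_cat[category])`.
#' @export
draw_stimulus <- function(task, category, n = 1) {
  stopifnot(inherits(task, "co_task"))
  if (!all(category %in% 1:2)) stop("category must be 1 or 2", call. = FALSE)
  category <- rep_len(as.integer(category), n)
  stats::rnorm(n, task$mu[category], task$sigma_cat[category])
}

# Block sequence for one task part of one session: category-training blocks
# alternate with testing blocks; confidence-training blocks follow the first
# category-training block.
part_block_sequence <- function(structure) {
  ct <- structure$category_training
  cf <- structure$confidence_training
  te <- structure$testing
  rows <- list()
  nb <- max(ct[1], te[1])
  for (b in seq_len(nb)) {
    if (b <= ct[1])
      rows[[length(rows) + 1]] <- list("category_training", b, ct[2])
    if (b == 1 && cf[1] > 0)
      for (cb in seq_len(cf[1]))
        rows[[length(rows) + 1]] <- list("confidence_training", cb, cf[2])
    if (b <= te[1])
      rows[[length(rows) + 1]] <- list("testing", b, te[2])
  }
  tibble::tibble(phase = vapply(rows, `[[`, character(1), 1),
                 block = vapply(rows, `[[`, integer(1), 2),
                 n = vapply(rows, `[[`, numeric(1), 3))
}

# Core (pre-lapse) response for a vector of trials of one task, given the
# realized measurement (x; the readout z for the linear neural model).
# Computed from the model's decision variable directly -- deliberately
# independent of the boundary-inversion route used by the likelihood.
core_response_sim <- function(model, dec, task, x, sigma_i, eta = 0) {
  fam <- model$family
  tk <- task$task_id
  conf <- model$response_mode == "choice_confidence"
  bel <- if (!is.null(dec$beliefs)) dec$beliefs[[tk]] else category_beliefs(task)
  cr <- dec$crit[[tk]]
  count_above <- function(val, k) {
    k <- sort(k)
    rowSums(outer(val, k, ">"))
  }
  if (cr$type == "bayes") {
    d <- log_posterior_ratio(task, x, sigma_i, bel) + eta
    return(as.integer(length(cr$k) + 1 - rowSums(outer(d, cr$k, ">"))))
  }
  if (cr$type == "hybrid") {
    d <- log_posterior_ratio(task, x, sigma_i, bel) + eta
    cat <- ifelse(d > cr$k4, 1L, 2L)
    if (!conf) return(cat)
    v <- hybrid_decision_variable(d, sigma_i, dec$extras$omega)
    lev <- 1L + as.integer(rowSums(outer(v, sort(cr$kv), ">")))
    return(choice_to_response(cat, lev))
  }
  if (fam == "linear_neural") {
    val <- if (tk == "A") x else abs(x)  # x is the readout z here
    k <- if (tk == "A") cr$k else pmax(cr$k, 0)
    return(as.integer(1 + count_above(val, k)))
  }
  if (fam == "orientation_estimation") {
    # MAP-estimate profile per unique sigma, then linear interpolation over
    # the measurement draws (the likelihood route inverts the profile
    # instead)
    x_grid <- seq(-90, 90, length.out = 2001)
    s_grid <- seq(-90, 90, by = 0.1)
    shat <- numeric(length(x))
    for (sg in unique(sigma_i)) {
      i <- which(sigma_i == sg)
      prof <- shat_profile(x_grid, sg, bel, s_grid)
      shat[i] <- stats::approx(x_grid, prof, xout = pmin(pmax(x[i], -90), 90),
                               rule = 2)$y
    }
    val <- if (tk == "A") shat else abs(shat)
    k <- if (tk == "A") cr$k else pmax(cr$k, 0)
    return(as.integer(1 + count_above(val, k)))
  }
  # fixed / lin / quad: compare the measurement to the boundary functions
  bnd <- heuristic_boundaries(cr$type, cr$k, cr$m, sigma_i, tk)
  val <- if (tk == "A") x else abs(x)
  as.integer(1 + rowSums(val > bnd))
}

# Apply the lapse mixture to realized core responses. One uniform draw
# selects the lapse type; two further uniforms (always drawn, to keep the
# per-trial draw count fixed) provide the lapsed category and confidence.
# Repeat lapses copy the realized previous response, so they are filled in a
# sequential pass; `first` marks trials with no previous response, whose
# repeat mass is renormalized away.
apply_lapse_sim <- function(resp_core, lapses, conf_mode, first) {
  n <- length(resp_core)
  u <- stats::runif(n)
  ucat <- stats::runif(n)
  uconf <- stats::runif(n)
  lr <- lapses$lambda_repeat %||% 0
  u[first] <- u[first] * (1 - lr)
  resp <- resp_core
  if (conf_mode) {
    lf <- lapses$lambda_full %||% 0
    lc <- lapses$lambda_conf %||% 0
    w <- conf_lapse_weights(lapses$lambda_1 %||% 0, lapses$lambda_4 %||% 0)
    is_full <- u < lf
    is_conf <- !is_full & u < lf + lc
    is_rep <- !is_full & !is_conf & u < lf + lc + lr
    if (any(is_full)) {
      cat <- ifelse(ucat[is_full] > 0.5, 2L, 1L)
      lev <- findInterval(uconf[is_full], cumsum(w)) + 1L
      resp[is_full] <- choice_to_response(cat, pmin(lev, 4L))
    }
    if (any(is_conf)) {
      cat <- ifelse(resp_core[is_conf] <= 4, 1L, 2L)
      lev <- pmin(floor(uconf[is_conf] * 4) + 1L, 4L)
      resp[is_conf] <- choice_to_response(cat, lev)
    }
  } else {
    lf <- lapses$lambda %||% 0
    is_rep <- u >= lf & u < lf + lr
    resp[u < lf] <- ifelse(ucat[u < lf] > 0.5, 2L, 1L)
  }
  if (any(is_rep)) {
    for (i in which(is_rep)) if (i > 1 && !first[i]) resp[i] <- resp[i - 1]
  }
  resp
}

# Generate responses for trials of one task part (in presentation order):
# measurement draw, optional decision-noise draw, core response, lapses.
gen_responses <- function(model, dec, task, s, sigma_m, sigma_i, first) {
  n <- length(s)
  if (model$family == "linear_neural") {
    mo <- linear_neural_moments(s, sigma_m, dec$extras$a, dec$extras$sigma_tc)
    x <- stats::rnorm(n, mo$mean, sqrt(mo$var))
  } else {
    x <- stats::rnorm(n, s, sigma_m)
  }
  eta <- if (model$d_noise) stats::rnorm(n, 0, dec$extras$sigma_d) else 0
  core <- core_response_sim(model, dec, task, x, sigma_i, eta)
  apply_lapse_sim(core, dec$lapses,
                  model$response_mode == "choice_confidence", first)
}

#' Generate a synthetic dataset with the experiment's session structure
#'
#' Simulates a full subject: for every session and task part, category
#' training (choice only, full stimulus strength), confidence training and
#' testing blocks, with per-trial draws in the documented order (category,
#' stimulus, reliability level, measurement, decision noise where present,
#' lapse). Testing and confidence-training trials draw one of the six
#' reliability levels uniformly; responses come from the supplied observer
#' model including its lapse processes. Training trials are generated for
#' structural fidelity only and are excluded from all fits.
#'
#' @param model A [model_spec()]; its scope determines which task parts get
#'   model responses (both parts are still generated).
#' @param theta Named sampling-scale parameter vector (e.g. from
#'   [draw_params()]).
#' @param structure A [session_structure()].
#' @param stimulus `"gabor"` or `"ellipse"` (sets the reliability preset).
#' @param tasks Optional named list of [task_spec()]s.
#' @param seed Integer seed; identical seeds give identical datasets.
#' @param subject_id,experiment_id Labels stored with each trial.
#' @param testing_only Skip the training phases (faster; used for fitting
#'   and recovery studies where training trials are never analyzed).
#' @return A tibble of trials (class `co_dataset`) with attributes `tasks`,
#'   `stimulus` and `provenance` (model name, parameters, seed).
#' @examples
#' m <- model_spec("fixed")
#' th <- draw_params(m, 1)[1, ]
#' d <- generate_dataset(m, th, seed = 1, testing_only = TRUE)
#' dplyr::count(d, task)
#' @export
generate_dataset <- function(model, theta, structure = session_structure(),
                             stimulus = c("gabor", "ellipse"), tasks = NULL,
                             seed = NULL, subject_id = "S01",
                             experiment_id = 1L, testing_only = FALSE) {
  stimulus <- match.arg(stimulus)
  stopifnot(inherits(model, "co_model"), inherits(structure, "co_session"))
  tasks <- tasks %||% default_tasks(stimulus)
  validate_theta(model, theta)
  dec <- decode_params(model, theta, tasks)
  if (!is.null(seed)) set.seed(seed)
  full_strength <- if (stimulus == "gabor") 1.0 else 0.95
  rel_values <- tasks[[1]]$reliability_values

  parts <- list()
  for (sess in seq_len(structure$n_sessions)) {
    for (tk in structure$tasks) {
      task <- tasks[[tk]]
      seq_tbl <- part_block_sequence(structure)
      if (testing_only)
        seq_tbl <- dplyr::filter(seq_tbl, .data$phase == "testing")
      if (!nrow(seq_tbl)) next
      ph <- rep(seq_tbl$phase, seq_tbl$n)
      blk <- rep(seq_tbl$block, seq_tbl$n)
      n <- length(ph)
      trial <- stats::ave(seq_len(n), ph, blk, FUN = seq_along)
      cat <- ifelse(stats::runif(n) < task$prior_c1, 1L, 2L)
      s <- draw_stimulus(task, cat, n)
      is_ct <- ph == "category_training"
      lvl <- rep(NA_integer_, n)
      lvl[!is_ct] <- sample.int(6, sum(!is_ct), replace = TRUE)
      relv <- ifelse(is_ct, full_strength, rel_values[lvl])

      resp <- rep(NA_integer_, n)
      in_scope <- tk %in% scope_tasks(model)
      # reliability used for the model's noise: training trials are shown at
      # full strength, outside the calibrated range; clamp to the highest
      # calibrated reliability for their (never-analyzed) responses
      rel_for_noise <- pmin(relv, max(rel_values))
      sig_arg <- if (dec$noise$mode == "nonparametric")
        ifelse(is_ct, 6L, lvl) else rel_for_noise
      sm <- sigma_of(dec$noise, sig_arg, s)
      si <- if (identical(dec$noise_infer, dec$noise)) sm else {
        sig_arg_i <- if (dec$noise_infer$mode == "nonparametric")
          ifelse(is_ct, 6L, lvl) else rel_for_noise
        sigma_of(dec$noise_infer, sig_arg_i, s)
      }
      if (in_scope) {
        first <- !duplicated(paste(ph, blk)) # no carry-over across blocks
        conf_part <- !is_ct
        # testing + confidence training: full response; category training:
        # choice only (no confidence buttons yet)
        if (any(!is_ct))
          resp[!is_ct] <- gen_responses(model, dec, task, s[!is_ct],
                                        sm[!is_ct], si[!is_ct],
                                        first[!is_ct])
        if (any(is_ct)) {
          x <- stats::rnorm(sum(is_ct), s[is_ct], sm[is_ct])
          eta <- if (model$d_noise)
            stats::rnorm(sum(is_ct), 0, dec$extras$sigma_d) else 0
          choice_model <- model
          choice_model$response_mode <- "choice_only"
          dec_choice <- dec
          dec_choice$crit <- lapply(dec$crit, collapse_to_choice)
          resp[is_ct] <- core_response_sim(choice_model, dec_choice, task,
                                           x, si[is_ct], eta)
        }
      }
      conf_mode <- model$response_mode == "choice_confidence"
      chosen <- ifelse(is.na(resp), NA_integer_,
                       ifelse(is_ct | !conf_mode, resp,
                              ifelse(resp <= 4, 1L, 2L)))
      confl <- ifelse(is.na(resp) | is_ct | !conf_mode, NA_integer_,
                      ifelse(resp <= 4, 5L - resp, resp - 4L))
      parts[[length(parts) + 1]] <- tibble::tibble(
        subject_id = subject_id, experiment = experiment_id, phase = ph,
        session = sess, block = blk, trial = trial, task = tk,
        true_category = cat, orientation_deg = s, reliability_level = lvl,
        reliability_value = relv,
        response = ifelse(is_ct | !conf_mode, NA_integer_, resp),
        chosen_category = chosen, confidence = confl)
    }
  }
  out <- dplyr::bind_rows(parts)
  attr(out, "tasks") <- tasks
  attr(out, "stimulus") <- stimulus
  attr(out, "provenance") <- list(model = model$name, theta = as.list(theta),
                                  seed = seed)
  class(out) <- c("co_dataset", class(out))
  out
}

# Reduce a confidence criterion set to its category criterion (for
# category-training responses of confidence models).
collapse_to_choice <- function(cr) {
  if (is.null(cr)) return(NULL)
  if (cr$type == "hybrid") return(cr)
  mid <- (length(cr$k) + 1) %/% 2
  cr$k <- cr$k[mid]
  if (!is.null(cr$m)) cr$m <- cr$m[mid]
  cr
}

validate_theta <- function(model, theta) {
  tab <- param_table(model)
  miss <- setdiff(tab$name, names(theta))
  if (length(miss))
    stop("invalid parameter vector; missing block entries: ",
         paste(miss, collapse = ", "), call. = FALSE)
  bad <- tab$name[theta[tab$name] < tab$lower_s - 1e-9 |
                    theta[tab$name] > tab$upper_s + 1e-9]
  if (length(bad))
    stop("parameters outside their declared range: ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Re-simulate responses on the stimuli of an existing dataset
#'
#' Keeps every trial's task, category, orientation and reliability, and
#' regenerates the responses of the testing trials from the given model and
#' parameters (used for posterior-predictive fit visualization and model
#' recovery, which replay the original stimulus sequences).
#'
#' @inheritParams generate_dataset
#' @param data A trial tibble.
#' @return The dataset with testing-phase responses replaced.
#' @export
simulate_responses <- function(data, model, theta, tasks = NULL, seed = NULL) {
  tasks <- tasks %||% attr(data, "tasks") %||% default_tasks()
  validate_theta(model, theta)
  dec <- decode_params(model, theta, tasks)
  if (!is.null(seed)) set.seed(seed)
  d <- data
  conf_mode <- model$response_mode == "choice_confidence"
  idx_all <- which(d$phase == "testing" & d$task %in% scope_tasks(model))
  ord <- idx_all[order(d$session[idx_all], d$task[idx_all], d$block[idx_all],
                       d$trial[idx_all])]
  for (tk in intersect(scope_tasks(model), unique(d$task))) {
    i <- ord[d$task[ord] == tk]
    if (!length(i)) next
    task <- tasks[[tk]]
    sub <- d[i, ]
    sig_arg <- if (dec$noise$mode == "nonparametric") sub$reliability_level
               else sub$reliability_value
    sm <- sigma_of(dec$noise, sig_arg, sub$orientation_deg)
    si <- if (identical(dec$noise_infer, dec$noise)) sm else {
      arg <- if (dec$noise_infer$mode == "nonparametric")
        sub$reliability_level else sub$reliability_value
      sigma_of(dec$noise_infer, arg, sub$orientation_deg)
    }
    first <- !duplicated(paste(sub$session, sub$block))
    resp <- gen_responses(model, dec, task, sub$orientation_deg, sm, si, first)
    d$response[i] <- if (conf_mode) resp else NA_integer_
    d$chosen_category[i] <- if (conf_mode) ifelse(resp <= 4, 1L, 2L) else resp
    d$confidence[i] <- if (conf_mode)
      ifelse(resp <= 4, 5L - resp, resp - 4L) else NA_integer_
  }
  d
}

#' Write / read a dataset as CSV with a provenance sidecar
#'
#' The CSV has one trial per row with the canonical column order; synthetic
#' datasets also get a `<path>.provenance.json` sidecar recording the
#' generating model, parameters and seed.
#'
#' @param data A trial tibble.
#' @param path CSV path.
#' @return `write_dataset()` the path, invisibly; `read_dataset()` the trial
#'   tibble (with provenance re-attached when the sidecar exists).
#' @export
write_dataset <- function(data, path) {
  cols <- c("subject_id", "experiment", "phase", "session", "block", "trial",
            "task", "true_category", "orientation_deg", "reliability_level",
            "reliability_value", "response", "chosen_category", "confidence")
  utils::write.csv(as.data.frame(data)[, cols], path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  prov <- attr(data, "provenance")
  if (!is.null(prov))
    jsonlite::write_json(prov, paste0(path, ".provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dataset
#' @param stimulus Stimulus type to assume when rebuilding the task specs.
#' @export
read_dataset <- function(path, stimulus = c("gabor", "ellipse")) {
  stimulus <- match.arg(stimulus)
  d <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  int_cols <- c("session", "block", "trial", "true_category",
                "reliability_level", "response", "chosen_category",
                "confidence")
  for (cc in intersect(int_cols, names(d))) d[[cc]] <- as.integer(d[[cc]])
  attr(d, "tasks") <- default_tasks(stimulus)
  attr(d, "stimulus") <- stimulus
  sidecar <- paste0(path, ".provenance.json")
  if (file.exists(sidecar))
    attr(d, "provenance") <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  class(d) <- c("co_dataset", class(d))
  d
}

#' Accuracy of the noiseless ideal observer
#'
#' With zero measurement noise and the optimal decision rule, Task A accuracy
#' is Phi(|mu_2 - mu_1| / (2 sigma_cat)) and Task B accuracy follows from the
#' likelihood-equality criterion |s*| with s*^2 = 2 log(sigma_2/sigma_1) /
#' (1/sigma_1^2 - 1/sigma_2^2). Both design values are close to 0.79. The
#' simulation method draws categories and stimuli and applies the optimal
#' rule directly.
#'
#' @param task A [task_spec()].
#' @param method `"analytic"` or `"simulate"`.
#' @param n Number of simulated trials.
#' @param seed Optional seed for the simulation.
#' @return Proportion correct (scalar).
#' @examples
#' ideal_observer_accuracy(task_spec("A"))  # pnorm(0.8)
#' @export
ideal_observer_accuracy <- function(task, method = c("analytic", "simulate"),
                                    n = 1e6, seed = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(task, "co_task"))
  if (task$task_id == "A") {
    mid <- mean(task$mu)
    acc_rule <- function(s, cat) ifelse(s < mid, 1L, 2L) == cat
    analytic <- 0.5 * (stats::pnorm((mid - task$mu[1]) / task$sigma_cat[1]) +
                       stats::pnorm((task$mu[2] - mid) / task$sigma_cat[2]))
  } else {
    s1 <- task$sigma_cat[1]; s2 <- task$sigma_cat[2]
    sstar <- sqrt(2 * log(s2 / s1) / (1 / s1^2 - 1 / s2^2))
    acc_rule <- function(s, cat) ifelse(abs(s) < sstar, 1L, 2L) == cat
    analytic <- 0.5 * ((2 * stats::pnorm(sstar / s1) - 1) +
                       2 * stats::pnorm(-sstar / s2))
  }
  if (method == "analytic") return(analytic)
  if (!is.null(seed)) set.seed(seed)
  cat <- ifelse(stats::runif(n) < task$prior_c1, 1L, 2L)
  s <- draw_stimulus(task, cat, n)
  mean(acc_rule(s, cat))
}
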