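CO_FAMILIES <- c("bayes_ultrastrong", "bayes_strong", "bayes_weak",
                 "fixed", "lin", "quad", "orientation_estimation",
                 "linear_neural", "precision_hybrid")

#' Specify an observer model
#'
#' An observer model is a family (which decision variable drives the
#' response) plus structural flags. Families:
#'
#' * `bayes_ultrastrong` / `bayes_strong` / `bayes_weak`: criteria on the log
#'   posterior ratio d. Ultrastrong: one symmetric criterion set shared by
#'   both tasks (4 boundary parameters in a joint fit). Strong: one symmetric
#'   set per task (8). Weak: symmetric for Task A, free for Task B (11).
#' * `fixed`, `lin`, `quad`: criteria directly in measurement space, constant
#'   / linear / quadratic in the sensory uncertainty sigma.
#' * `orientation_estimation`: criteria on the MAP orientation estimate.
#' * `linear_neural`: criteria on a linear readout of a Poisson population.
#' * `precision_hybrid`: confidence criteria on a weighted mixture of
#'   precision (1/sigma^2) and perceived probability correct; one
#'   ultrastrong-style 4-criterion set. Orientation-dependent noise is
#'   excluded for this family.
#'
#' @param family One of the families above.
#' @param d_noise Add trial-level Gaussian noise on d (Bayesian families and
#'   the precision hybrid only), marginalized over a [dnoise_grid()].
#' @param free_category_params Fit the believed category s.d.s and log prior
#'   ratio instead of using the true values.
#' @param noise_split Fit separate generative (measurement) and believed
#'   (inference) noise parameters.
#' @param nonparam_sigma Replace the power-law reliability-noise relationship
#'   with one free s.d. per reliability level.
#' @param fit_scope `"jointAB"`, `"taskA"` or `"taskB"`: which tasks the
#'   model is fit to.
#' @param response_mode `"choice_confidence"` (responses 1-8) or
#'   `"choice_only"` (category choice, responses collapse to 2).
#' @param orientation_dep_noise Include the orientation-dependent noise term
#'   psi (default `TRUE` except for `precision_hybrid`).
#' @return An object of class `co_model`.
#' @examples
#' model_spec("bayes_weak", d_noise = TRUE)   # the paper-style core Bayes model
#' model_spec("quad")
#' @export
model_spec <- function(family = CO_FAMILIES, d_noise = FALSE,
                       free_category_params = FALSE, noise_split = FALSE,
                       nonparam_sigma = FALSE,
                       fit_scope = c("jointAB", "taskA", "taskB"),
                       response_mode = c("choice_confidence", "choice_only"),
                       orientation_dep_noise = NULL) {
  family <- match.arg(family)
  fit_scope <- match.arg(fit_scope)
  response_mode <- match.arg(response_mode)
  if (is.null(orientation_dep_noise))
    orientation_dep_noise <- family != "precision_hybrid"
  if (d_noise && !family %in% c("bayes_ultrastrong", "bayes_strong",
                                "bayes_weak", "precision_hybrid"))
    stop("d_noise is only defined for the Bayesian families and the ",
         "precision hybrid", call. = FALSE)
  if (noise_split && family %in% c("fixed", "linear_neural"))
    stop("noise_split requires a model whose decision rule uses sigma",
         call. = FALSE)
  name <- paste0(family,
                 if (d_noise) "_dn" else "",
                 if (nonparam_sigma) "_npsigma" else "",
                 if (noise_split) "_split" else "",
                 if (free_category_params) "_freecat" else "",
                 if (response_mode == "choice_only") "_choice" else "")
  structure(list(family = family, d_noise = d_noise,
                 free_category_params = free_category_params,
                 noise_split = noise_split, nonparam_sigma = nonparam_sigma,
                 fit_scope = fit_scope, response_mode = response_mode,
                 orientation_dep_noise = orientation_dep_noise, name = name),
            class = "co_model")
}

#' @export
print.co_model <- function(x, ...) {
  cat(sprintf("<co_model %s> scope %s, %s\n", x$name, x$fit_scope,
              x$response_mode))
  invisible(x)
}

#' Registry of canonical model names
#'
#' The core comparison set of the confidence analysis plus the stronger
#' Bayesian variants. `model_from_name()` rebuilds a [model_spec()] from a
#' canonical name (suffixes: `_dn` decision noise, `_npsigma` nonparametric
#' noise, `_split` separate believed noise, `_freecat` free category
#' parameters, `_choice` choice-only).
#'
#' @return `model_registry()`: a tibble with columns `name` and `family`.
#' @export
model_registry <- function() {
  core <- c("bayes_weak_dn", "bayes_weak", "bayes_strong", "bayes_ultrastrong",
            "fixed", "lin", "quad", "orientation_estimation", "linear_neural",
            "precision_hybrid")
  tibble::tibble(name = core,
                 family = vapply(core, function(n) model_from_name(n)$family,
                                 character(1)))
}

#' @rdname model_registry
#' @param name Canonical model name.
#' @param ... Passed on to [model_spec()] (e.g. `fit_scope`).
#' @export
model_from_name <- function(name, ...) {
  fam <- CO_FAMILIES[which.max(vapply(CO_FAMILIES, function(f)
    ifelse(startsWith(name, f), nchar(f), 0L), integer(1)))]
  if (!startsWith(name, fam)) stop("unknown model name: ", name, call. = FALSE)
  suffix <- substring(name, nchar(fam) + 1)
  model_spec(fam,
             d_noise = grepl("_dn", suffix, fixed = TRUE),
             nonparam_sigma = grepl("_npsigma", suffix, fixed = TRUE),
             noise_split = grepl("_split", suffix, fixed = TRUE),
             free_category_params = grepl("_freecat", suffix, fixed = TRUE),
             response_mode = if (grepl("_choice", suffix, fixed = TRUE))
               "choice_only" else "choice_confidence",
             ...)
}

scope_tasks <- function(model) {
  switch(model$fit_scope, jointAB = c("A", "B"), taskA = "A", taskB = "B")
}

#' Serialize / restore a model specification as JSON
#'
#' The JSON object carries the family and every structural flag; reading
#' revalidates through [model_spec()], so invalid combinations are rejected.
#'
#' @param model A [model_spec()].
#' @param path JSON file path.
#' @return `write_model_spec()` the path, invisibly; `read_model_spec()` a
#'   `co_model`.
#' @export
write_model_spec <- function(model, path) {
  stopifnot(inherits(model, "co_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  model_spec(family = x$family, d_noise = isTRUE(x$d_noise),
             free_category_params = isTRUE(x$free_category_params),
             noise_split = isTRUE(x$noise_split),
             nonparam_sigma = isTRUE(x$nonparam_sigma),
             fit_scope = x$fit_scope, response_mode = x$response_mode,
             orientation_dep_noise = isTRUE(x$orientation_dep_noise))
}

# ---- Parameter table ------------------------------------------------------

ptrow <- function(name, block, lower, upper, scale = "linear") {
  tibble::tibble(name = name, block = block, lower = lower, upper = upper,
                 scale = scale)
}

boundary_param_names <- function(model) {
  tasks <- scope_tasks(model)
  fam <- model$family
  conf <- model$response_mode == "choice_confidence"
  if (fam %in% c("bayes_ultrastrong", "precision_hybrid")) {
    if (!conf) return("k_4")
    if (fam == "precision_hybrid") return(c("kv_1", "kv_2", "kv_3", "k_4"))
    return(paste0("k_", 1:4))
  }
  if (fam == "bayes_strong") {
    idx <- if (conf) 1:4 else 4
  } else if (fam == "bayes_weak") {
    out <- character(0)
    if ("A" %in% tasks) out <- c(out, paste0("ka_", if (conf) 1:4 else 4))
    if ("B" %in% tasks) out <- c(out, paste0("kb_", if (conf) 1:7 else 4))
    return(out)
  } else {
    idx <- if (conf) 1:7 else 4
  }
  out <- character(0)
  if ("A" %in% tasks) out <- c(out, paste0("ka_", idx))
  if ("B" %in% tasks) out <- c(out, paste0("kb_", idx))
  out
}

#' Free-parameter table of a model
#'
#' One row per free parameter: name, block (noise, boundary, slope, extra,
#' beliefs, lapse), prior range on the natural scale, and sampling scale
#' (parameters defining the width of a distribution are sampled in log
#' space). Priors are uniform on the sampling scale (hence log-uniform on the
#' natural scale for `scale == "log"`), over deliberately wide default
#' ranges; override ranges by editing the returned tibble and passing it to
#' the fitting functions.
#'
#' @param model A [model_spec()].
#' @return A tibble with columns `name`, `block`, `lower`, `upper`, `scale`,
#'   and sampling-scale bounds `lower_s`, `upper_s`.
#' @examples
#' nrow(dplyr::filter(param_table(model_spec("bayes_weak")), block == "boundary"))  # 11
#' @export
param_table <- function(model) {
  stopifnot(inherits(model, "co_model"))
  key <- paste(model$name, model$fit_scope)
  hit <- .co_cache$param_table[[key]]
  if (!is.null(hit)) return(hit)
  fam <- model$family
  conf <- model$response_mode == "choice_confidence"
  rows <- list()
  noise_block <- function(prefix = "") {
    r <- list()
    if (model$nonparam_sigma) {
      r <- c(r, list(ptrow(paste0(prefix, "sigma_rel_", 1:6), "noise",
                           0.1, 50, "log")))
    } else {
      r <- c(r, list(ptrow(paste0(prefix, c("sigma_low", "sigma_high")),
                           "noise", 0.1, 50, "log"),
                     ptrow(paste0(prefix, "beta"), "noise", 0.1, 10, "log")))
    }
    if (model$orientation_dep_noise)
      r <- c(r, list(ptrow(paste0(prefix, "psi"), "noise", 0, 10)))
    r
  }
  rows <- c(rows, noise_block())
  if (model$noise_split) rows <- c(rows, noise_block("infer_"))

  knames <- boundary_param_names(model)
  krange <- switch(fam,
                   bayes_ultrastrong = , bayes_strong = , bayes_weak = c(-20, 20),
                   linear_neural = c(-1e5, 1e5),
                   precision_hybrid = c(-20, 20),  # k_4 on d; kv rows set below
                   c(-90, 90))
  rows <- c(rows, list(ptrow(knames, "boundary", krange[1], krange[2])))
  if (fam == "precision_hybrid" && conf) {
    # confidence criteria on v live on [0, 200] (v = omega/sigma^2 + p)
    rows[[length(rows)]] <- dplyr::bind_rows(
      ptrow(c("kv_1", "kv_2", "kv_3"), "boundary", 0, 200),
      ptrow("k_4", "boundary", -20, 20))
  }
  if (fam %in% c("lin", "quad")) {
    mnames <- sub("^k", "m", knames)
    rows <- c(rows, list(ptrow(mnames, "slope", -90, 90)))
  }
  if (model$d_noise)
    rows <- c(rows, list(ptrow("sigma_d", "extra", 0.01, 10, "log")))
  if (fam == "linear_neural")
    rows <- c(rows, list(ptrow("a", "extra", 1e-3, 1e2, "log"),
                         ptrow("sigma_tc", "extra", 0.5, 100, "log")))
  if (fam == "precision_hybrid")
    rows <- c(rows, list(ptrow("omega", "extra", 0, 100)))
  if (model$free_category_params) {
    tasks <- scope_tasks(model)
    if ("A" %in% tasks)
      rows <- c(rows, list(ptrow("bel_sigma_a", "beliefs", 0.1, 50, "log")))
    if ("B" %in% tasks)
      rows <- c(rows, list(ptrow(c("bel_sigma_b1", "bel_sigma_b2"),
                                 "beliefs", 0.1, 50, "log")))
    rows <- c(rows, list(ptrow("bel_lpr", "beliefs", -3, 3)))
  }
  if (conf) {
    rows <- c(rows, list(ptrow("lambda_full", "lapse", 0, 0.3),
                         ptrow(c("lambda_1", "lambda_4"), "lapse", 0, 1),
                         ptrow(c("lambda_conf", "lambda_repeat"), "lapse",
                               0, 0.3)))
  } else {
    rows <- c(rows, list(ptrow(c("lambda", "lambda_repeat"), "lapse", 0, 0.3)))
  }
  tab <- dplyr::bind_rows(rows)
  lg <- tab$scale == "log"
  tab$lower_s <- tab$lower
  tab$upper_s <- tab$upper
  tab$lower_s[lg] <- log(tab$lower[lg])
  tab$upper_s[lg] <- log(tab$upper[lg])
  .co_cache$param_table[[key]] <- tab
  tab
}

# per-session cache for derived tables (parameter layouts are pure functions
# of the model spec)
.co_cache <- new.env(parent = emptyenv())
.co_cache$param_table <- list()

#' Export a model's parameter table as CSV
#'
#' One row per free parameter (name, block, prior range, sampling scale).
#'
#' @param model A [model_spec()].
#' @param path Output CSV path.
#' @return The parameter table, invisibly.
#' @export
export_param_table <- function(model, path) {
  tab <- param_table(model)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}

# sampling scale -> natural scale, as a named numeric vector
natural_params <- function(theta, table) {
  v <- theta[table$name]
  v[table$scale == "log"] <- exp(v[table$scale == "log"])
  v
}

# natural scale -> sampling scale
sampling_params <- function(values, table) {
  v <- values[table$name]
  v[table$scale == "log"] <- log(v[table$scale == "log"])
  v
}

# Expand symmetric criterion parameters (k1..k4) into the full ascending
# 7-vector (k1, k2, k3, k4, 2 k4 - k3, 2 k4 - k2, 2 k4 - k1).
symmetric_criteria <- function(k14) {
  k4 <- k14[4]
  c(k14, 2 * k4 - k14[3:1])
}

#' Decode a sampling-scale parameter vector into model components
#'
#' @param model A [model_spec()].
#' @param theta Named numeric vector on the sampling scale (as produced by
#'   [draw_params()] or the fitting functions).
#' @param tasks Named list of [task_spec()]s (`A` and/or `B`), used for the
#'   reliability calibration range.
#' @return A list with components `noise`, `noise_infer` ([noise_params()]
#'   objects), `crit` (per-task criterion sets), `lapses`, `extras` and
#'   `beliefs` (per-task [category_beliefs()] overrides or `NULL`).
#' @keywords internal
#' @export
decode_params <- function(model, theta, tasks) {
  tab <- param_table(model)
  miss <- setdiff(tab$name, names(theta))
  if (length(miss))
    stop("parameter vector is missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  v <- as.list(natural_params(theta, tab))
  rel_values <- tasks[[1]]$reliability_values
  mk_noise <- function(prefix = "") {
    psi <- if (model$orientation_dep_noise) v[[paste0(prefix, "psi")]] else 0
    if (model$nonparam_sigma) {
      noise_params(sigma_per_level =
                     unlist(v[paste0(prefix, "sigma_rel_", 1:6)]),
                   psi = psi, reliability_values = rel_values)
    } else {
      noise_params(sigma_low = v[[paste0(prefix, "sigma_low")]],
                   sigma_high = v[[paste0(prefix, "sigma_high")]],
                   beta = v[[paste0(prefix, "beta")]], psi = psi,
                   reliability_range = range(rel_values))
    }
  }
  noise <- mk_noise()
  noise_infer <- if (model$noise_split) mk_noise("infer_") else noise
  conf <- model$response_mode == "choice_confidence"
  fam <- model$family
  stasks <- scope_tasks(model)

  crit <- list()
  for (tk in stasks) {
    pfx <- if (fam %in% c("bayes_ultrastrong", "precision_hybrid")) "k_"
           else if (tk == "A") "ka_" else "kb_"
    if (fam == "precision_hybrid") {
      crit[[tk]] <- list(type = "hybrid",
                         kv = if (conf) unlist(v[paste0("kv_", 1:3)]) else NULL,
                         k4 = v[["k_4"]])
    } else if (fam %in% c("bayes_ultrastrong", "bayes_strong", "bayes_weak")) {
      if (!conf) {
        kfull <- v[[paste0(pfx, 4)]]
      } else if (fam == "bayes_weak" && tk == "B") {
        kfull <- unlist(v[paste0(pfx, 1:7)])
      } else {
        kfull <- symmetric_criteria(unlist(v[paste0(pfx, 1:4)]))
      }
      crit[[tk]] <- list(type = "bayes", k = unname(kfull))
    } else {
      idx <- if (conf) 1:7 else 4
      k <- unlist(v[paste0(pfx, idx)])
      m <- if (fam %in% c("lin", "quad"))
        unlist(v[paste0(sub("k", "m", pfx), idx)]) else NULL
      crit[[tk]] <- list(type = fam, k = unname(k),
                         m = if (!is.null(m)) unname(m))
    }
  }

  lapses <- if (conf) {
    list(lambda_full = v$lambda_full, lambda_1 = v$lambda_1,
         lambda_4 = v$lambda_4, lambda_conf = v$lambda_conf,
         lambda_repeat = v$lambda_repeat)
  } else {
    list(lambda = v$lambda, lambda_repeat = v$lambda_repeat)
  }

  beliefs <- NULL
  if (model$free_category_params) {
    beliefs <- list()
    for (tk in stasks) {
      task <- tasks[[tk]]
      sc <- if (tk == "A") rep(v$bel_sigma_a, 2)
            else c(v$bel_sigma_b1, v$bel_sigma_b2)
      beliefs[[tk]] <- category_beliefs(task, sigma_cat = sc,
                                        log_prior_ratio = v$bel_lpr)
    }
  }
  list(noise = noise, noise_infer = noise_infer, crit = crit, lapses = lapses,
       extras = list(sigma_d = v$sigma_d, a = v$a, sigma_tc = v$sigma_tc,
                     omega = v$omega),
       beliefs = beliefs)
}

#' Draw parameter vectors for a model
#'
#' `source = "prior"` draws uniformly from the prior box on the sampling
#' scale. `source = "plausible"` draws from a narrower generating
#' distribution emulating typical human observers in this paradigm (noise of
#' a few degrees at high reliability, ordered criteria a few degrees or a
#' fraction of a log-odds unit apart, small lapse rates); it is the default
#' source for synthetic-data generation in the recovery harness, where raw
#' prior-box draws would mostly produce degenerate response data.
#'
#' @param model A [model_spec()].
#' @param n Number of draws.
#' @param source `"plausible"` or `"prior"`.
#' @param table Optional [param_table()] override.
#' @return An `n` x n_params matrix (sampling scale) with parameter names as
#'   column names.
#' @export
draw_params <- function(model, n = 1, source = c("plausible", "prior"),
                        table = param_table(model)) {
  source <- match.arg(source)
  if (source == "prior") {
    m <- vapply(seq_len(nrow(table)), function(j)
      stats::runif(n, table$lower_s[j], table$upper_s[j]), numeric(n))
    m <- matrix(m, nrow = n)
    colnames(m) <- table$name
    return(m)
  }
  m <- matrix(NA_real_, n, nrow(table), dimnames = list(NULL, table$name))
  for (i in seq_len(n)) m[i, ] <- plausible_draw(model, table)
  m
}

# One plausible natural-scale draw, returned on the sampling scale.
plausible_draw <- function(model, table) {
  fam <- model$family
  conf <- model$response_mode == "choice_confidence"
  v <- stats::setNames(numeric(nrow(table)), table$name)
  ru <- function(lo, hi, n = 1) stats::runif(n, lo, hi)
  set <- function(nm, val) { v[nm] <<- val; invisible(NULL) }

  noise_vals <- function(prefix = "") {
    sl <- ru(8, 20); sh <- ru(1, 3); be <- ru(0.6, 2.5)
    if (model$nonparam_sigma) {
      np <- noise_params(sl, sh, be, psi = 0)
      lev <- sigma_of(np, reliability_preset())
      set(paste0(prefix, "sigma_rel_", 1:6), lev * exp(ru(-0.05, 0.05, 6)))
    } else {
      set(paste0(prefix, "sigma_low"), sl)
      set(paste0(prefix, "sigma_high"), sh)
      set(paste0(prefix, "beta"), be)
    }
    if (model$orientation_dep_noise) set(paste0(prefix, "psi"), ru(0, 1.5))
    c(low = sl, high = sh)
  }
  ns <- noise_vals()
  if (model$noise_split) noise_vals("infer_")

  gaps_around <- function(center, glo, ghi) {
    c(center - rev(cumsum(ru(glo, ghi, 3))), center, center + cumsum(ru(glo, ghi, 3)))
  }
  for (tk in scope_tasks(model)) {
    pfx <- if (fam %in% c("bayes_ultrastrong", "precision_hybrid")) "k_"
           else if (tk == "A") "ka_" else "kb_"
    if (fam %in% c("bayes_ultrastrong", "bayes_strong", "bayes_weak")) {
      k4 <- ru(-0.3, 0.3)
      if (!conf) { set(paste0(pfx, 4), k4) }
      else if (fam == "bayes_weak" && tk == "B") {
        set(paste0(pfx, 1:7), gaps_around(k4, 0.4, 1.2))
      } else {
        set(paste0(pfx, 1:4), c(k4 - rev(cumsum(ru(0.4, 1.2, 3))), k4))
      }
      if (fam %in% c("bayes_ultrastrong")) break
    } else if (fam == "precision_hybrid") {
      set("k_4", ru(-0.3, 0.3))  # kv set below, once omega is drawn
      break
    } else if (fam == "linear_neural") {
      k4 <- ru(-5, 5)
      if (conf) set(paste0(pfx, 1:7), gaps_around(k4, 5, 25))
      else set(paste0(pfx, 4), k4)
    } else {
      glo <- if (fam == "fixed") 1.5 else 0.5
      ghi <- if (fam == "fixed") 5 else 2.5
      if (tk == "A") {
        k4 <- ru(-1.5, 1.5)
        kk <- gaps_around(k4, glo, ghi)
      } else {
        kk <- ru(1, 4) + c(0, cumsum(ru(glo, ghi, 6)))
      }
      if (conf) set(paste0(pfx, 1:7), kk) else set(paste0(pfx, 4), kk[4])
      if (fam %in% c("lin", "quad")) {
        scale <- if (fam == "lin") ru(0.4, 1.2) else ru(0.02, 0.1)
        mpfx <- sub("k", "m", pfx)
        if (tk == "A") {
          mm <- scale * ((1:7) - 4) / 3 + stats::rnorm(7, 0, scale / 20)
        } else {
          mm <- scale * (1:7) / 4 + stats::rnorm(7, 0, scale / 20)
        }
        if (conf) set(paste0(mpfx, 1:7), mm) else set(paste0(mpfx, 4), mm[4])
      }
    }
  }
  if (model$d_noise) set("sigma_d", ru(0.3, 1.5))
  if (fam == "linear_neural") { set("a", exp(ru(log(0.5), log(2))))
                                set("sigma_tc", ru(5, 30)) }
  if (fam == "precision_hybrid") {
    set("omega", ru(1, 10))
    if (conf) {
      # confidence criteria straddle typical v values at mid uncertainty
      sig_mid <- sqrt(mean(c(ns["low"]^2, ns["high"]^2)))
      set(paste0("kv_", 1:3),
          v["omega"] / sig_mid^2 + sort(ru(0.55, 0.95, 3)))
    }
  }
  if (model$free_category_params) {
    if ("A" %in% scope_tasks(model)) set("bel_sigma_a", ru(3, 7))
    if ("B" %in% scope_tasks(model)) {
      set("bel_sigma_b1", ru(2, 5)); set("bel_sigma_b2", ru(8, 16))
    }
    set("bel_lpr", ru(-0.5, 0.5))
  }
  if (conf) {
    set("lambda_full", ru(0.01, 0.06)); set("lambda_1", ru(0.3, 0.7))
    set("lambda_4", ru(0.1, 0.5)); set("lambda_conf", ru(0.01, 0.05))
    set("lambda_repeat", ru(0.005, 0.03))
  } else {
    set("lambda", ru(0.01, 0.06)); set("lambda_repeat", ru(0.005, 0.03))
  }
  # clamp into the prior box and return on the sampling scale
  v <- pmin(pmax(v, table$lower), table$upper)
  sampling_params(v, table)
}
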