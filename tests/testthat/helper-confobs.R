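# Shared fixtures: small structures, deterministic parameter draws, and the
# Monte-Carlo oracle comparing analytic response probabilities with
# simulated response frequencies.

small_structure <- function(n_testing = 144, tasks = c("A", "B")) {
  session_structure(n_sessions = 1, tasks = tasks,
                    category_training = c(1, 8),
                    confidence_training = c(1, 4),
                    testing = c(1, n_testing))
}

# deterministic plausible parameter vector for a model
fixed_theta <- function(model, seed = 99) {
  withr::with_seed(seed, draw_params(model, 1, source = "plausible")[1, ])
}

# one fake testing trial row per condition, for core_response_probabilities
condition_trials <- function(task_id, s, reliability_level,
                             stimulus = "gabor") {
  rel <- reliability_preset(stimulus)
  grid <- expand.grid(orientation_deg = s, reliability_level = reliability_level)
  tibble::tibble(
    subject_id = "cond", experiment = 1L, phase = "testing", session = 1L,
    block = 1L, trial = seq_len(nrow(grid)), task = task_id,
    true_category = 1L, orientation_deg = grid$orientation_deg,
    reliability_level = as.integer(grid$reliability_level),
    reliability_value = rel[grid$reliability_level],
    response = 1L, chosen_category = 1L, confidence = 4L)
}

# Monte-Carlo oracle: for each (task, reliability, stimulus) condition,
# simulate n measurement draws through the model's decision + lapse process
# and compare the response frequencies to the analytic probabilities.
# Returns the fraction of (condition x response) cells within `n_se`
# binomial standard errors.
mc_cell_agreement <- function(model, theta, s_values, n = 1e5, n_se = 4,
                              levels = 1:6, seed = 1) {
  set.seed(seed)
  tasks <- confobs:::default_tasks("gabor")
  theta <- theta[param_table(model)$name]
  # no repeat lapse: conditions are i.i.d. draws
  theta[names(theta) == "lambda_repeat"] <- 0
  dec <- confobs:::decode_params(model, theta, tasks)
  ok <- 0L; total <- 0L
  for (tk in scope_tasks_pub(model)) {
    task <- tasks[[tk]]
    svals <- s_values[[tk]]
    trials <- condition_trials(tk, svals, levels)
    probs <- core_response_probabilities(trials, model, theta)
    probs <- apply_lapses(probs, dec$lapses)
    for (ci in seq_len(nrow(trials))) {
      s <- trials$orientation_deg[ci]
      lvl <- trials$reliability_level[ci]
      sm <- sigma_of(dec$noise, if (dec$noise$mode == "nonparametric") lvl
                     else trials$reliability_value[ci], s)
      si <- if (identical(dec$noise_infer, dec$noise)) sm
            else sigma_of(dec$noise_infer, trials$reliability_value[ci], s)
      resp <- confobs:::gen_responses(model, dec, task, rep(s, n),
                                      rep(sm, n), rep(si, n),
                                      rep(FALSE, n))
      emp <- tabulate(resp, nbins = ncol(probs)) / n
      p <- probs[ci, ]
      se <- sqrt(pmax(p * (1 - p), 1e-12) / n)
      ok <- ok + sum(abs(emp - p) <= n_se * se + 1e-12)
      total <- total + length(p)
    }
  }
  ok / total
}

scope_tasks_pub <- function(model) {
  switch(model$fit_scope, jointAB = c("A", "B"), taskA = "A", taskB = "B")
}

# Conjugate Gaussian-mean fixture with exact leave-one-out (oracle for
# WAIC / PSIS-LOO checks).
conjugate_fixture <- function(n_obs = 50, n_draws = 4000, seed = 2) {
  # y_i ~ N(mu, 1), flat prior; posterior N(ybar, 1/n); everything closed form
  set.seed(seed)
  y <- rnorm(n_obs, 0.7, 1)
  mu_draws <- rnorm(n_draws, mean(y), sqrt(1 / n_obs))
  ll <- vapply(y, function(yi) dnorm(yi, mu_draws, 1, log = TRUE),
               numeric(n_draws))
  # exact leave-one-out predictive: y_i | y_{-i} ~ N(mean_{-i}, 1 + 1/(n-1))
  exact <- vapply(seq_len(n_obs), function(i)
    dnorm(y[i], mean(y[-i]), sqrt(1 + 1 / (n_obs - 1)), log = TRUE),
    numeric(1))
  list(y = y, ll = ll, exact_loo = sum(exact))
}

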