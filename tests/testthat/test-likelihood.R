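test_that("response probabilities are a partition for every family", {
  s_vals <- c(-9, -1, 0, 2, 14)
  for (nm in c("fixed", "lin", "quad", "bayes_ultrastrong", "bayes_strong",
               "bayes_weak", "bayes_weak_dn", "orientation_estimation",
               "linear_neural", "precision_hybrid")) {
    m <- model_from_name(nm)
    for (i in 1:5) {
      th <- withr::with_seed(100 + i, draw_params(m, 1, "plausible")[1, ])
      for (tk in c("A", "B")) {
        p <- core_response_probabilities(condition_trials(tk, s_vals, c(1, 4, 6)),
                                         m, th)
        expect_equal(rowSums(p), rep(1, nrow(p)), tolerance = 1e-6,
                     info = paste(nm, tk))
        expect_true(all(p >= -1e-12))
      }
    }
  }
})

test_that("lapse mixture matches its definition", {
  core <- c(0.05, 0.1, 0.15, 0.2, 0.2, 0.15, 0.1, 0.05)
  none <- list(lambda_full = 0, lambda_1 = 0, lambda_4 = 0, lambda_conf = 0,
               lambda_repeat = 0)
  expect_equal(apply_lapses(core, none), core)

  rep1 <- list(lambda_full = 0, lambda_conf = 0, lambda_repeat = 1)
  expect_equal(apply_lapses(core, rep1, previous_response = 3),
               c(0, 0, 1, 0, 0, 0, 0, 0))

  # equal endpoint weights: full-lapse confidence distribution is uniform;
  # checked against direct enumeration of the mixture
  lap <- list(lambda_full = 0.1, lambda_1 = 0.25, lambda_4 = 0.25,
              lambda_conf = 0.2, lambda_repeat = 0.08)
  out <- apply_lapses(core, lap, previous_response = 7)
  pcat1 <- sum(core[1:4])
  manual <- (1 - 0.1 - 0.2 - 0.08) * core +
    0.1 * rep(0.5 * 0.25, 8) +
    0.2 * c(rep(pcat1 / 4, 4), rep((1 - pcat1) / 4, 4)) +
    0.08 * (seq_len(8) == 7)
  expect_equal(out, manual)
  expect_equal(sum(out), 1)
  expect_true(all(out > 0))

  # first trial: repeat mass renormalized over remaining components
  out1 <- apply_lapses(core, lap, previous_response = NA)
  expect_equal(out1, (manual - 0.08 * (seq_len(8) == 7)) / 0.92)
  expect_equal(sum(out1), 1)

  # choice-only mode
  out2 <- apply_lapses(c(0.7, 0.3), list(lambda = 0.2, lambda_repeat = 0),
                       previous_response = NULL)
  expect_equal(out2, 0.8 * c(0.7, 0.3) + 0.1)
})

test_that("interpolated full-lapse confidence weights are normalized", {
  w <- confobs:::conf_lapse_weights(0.6, 0.1)
  expect_equal(sum(w), 1)
  expect_equal(diff(w), rep(diff(w)[1], 3))  # linear in level
  expect_equal(confobs:::conf_lapse_weights(0, 0), rep(0.25, 4))
})

test_that("dataset log likelihood is additive and order-invariant without repeats", {
  m <- model_spec("quad")
  th <- fixed_theta(m)
  th["lambda_repeat"] <- 0
  d <- generate_dataset(m, th, small_structure(60), seed = 3,
                        testing_only = TRUE)
  res <- dataset_log_likelihood(d, m, th, pointwise = TRUE)
  expect_equal(res$loglik, sum(res$pointwise))
  # per-trial recomputation, one trial at a time
  single <- vapply(seq_len(nrow(d)), function(i)
    dataset_log_likelihood(d[i, ], m, th), numeric(1))
  expect_equal(res$loglik, sum(single), tolerance = 1e-10)
  # permuting rows changes nothing when lambda_repeat = 0 (presentation
  # order is defined by the session/block/trial keys, not row order)
  set.seed(9)
  perm <- d[sample(nrow(d)), ]
  expect_equal(dataset_log_likelihood(perm, m, th), res$loglik)
  # reversing the presentation order matters once the repeat lapse is on
  th2 <- th
  th2["lambda_repeat"] <- 0.2  # lapse rates sample on the linear scale
  rev_d <- dplyr::mutate(d, trial = rev(trial),
                         .by = c("session", "task", "block"))
  expect_equal(dataset_log_likelihood(rev_d, m, th),
               dataset_log_likelihood(d, m, th))  # invariant without repeats
  ll_orig <- dataset_log_likelihood(d, m, th2)
  ll_rev <- dataset_log_likelihood(rev_d, m, th2)
  expect_false(isTRUE(all.equal(ll_orig, ll_rev)))
})

test_that("Fixed is exactly nested in Lin and Quad, Ultrastrong in Weak", {
  mf <- model_spec("fixed")
  thf <- fixed_theta(mf)
  d <- generate_dataset(mf, thf, small_structure(80), seed = 4,
                        testing_only = TRUE)
  llf <- dataset_log_likelihood(d, mf, thf)
  for (fam in c("lin", "quad")) {
    mm <- model_spec(fam)
    thm <- c(thf, setNames(rep(0, 14), paste0(rep(c("ma_", "mb_"), each = 7),
                                              1:7)))
    expect_equal(dataset_log_likelihood(d, mm, thm), llf, tolerance = 1e-12)
  }
  mu <- model_spec("bayes_ultrastrong")
  thu <- fixed_theta(mu)
  llu <- dataset_log_likelihood(d, mu, thu)
  mw <- model_spec("bayes_weak")
  ks <- confobs:::symmetric_criteria(unname(thu[paste0("k_", 1:4)]))
  thw <- c(thu[c("sigma_low", "sigma_high", "beta", "psi", "lambda_full",
                 "lambda_1", "lambda_4", "lambda_conf", "lambda_repeat")],
           setNames(unname(thu[paste0("k_", 1:4)]), paste0("ka_", 1:4)),
           setNames(ks, paste0("kb_", 1:7)))
  expect_equal(dataset_log_likelihood(d, mw, thw), llu, tolerance = 1e-12)
})

test_that("compiled and reference likelihood paths agree to machine precision", {
  cases <- list(
    model_spec("fixed"),
    model_spec("lin", fit_scope = "taskB"),
    model_spec("quad", response_mode = "choice_only"),
    model_spec("bayes_weak"),
    model_spec("bayes_strong", noise_split = TRUE),
    model_spec("bayes_ultrastrong", nonparam_sigma = TRUE),
    model_spec("bayes_weak", free_category_params = TRUE))
  for (m in cases) {
    th <- fixed_theta(m, seed = 31)
    d <- generate_dataset(m, th, small_structure(50), seed = 5,
                          testing_only = TRUE)
    a <- dataset_log_likelihood(d, m, th, engine = "r", pointwise = TRUE)
    b <- dataset_log_likelihood(d, m, th, engine = "cpp", pointwise = TRUE)
    expect_equal(a$pointwise, b$pointwise, tolerance = 1e-13, info = m$name)
  }
  expect_error(dataset_log_likelihood(
    generate_dataset(model_spec("fixed"), fixed_theta(model_spec("fixed")),
                     small_structure(10), seed = 1, testing_only = TRUE),
    model_spec("orientation_estimation"),
    fixed_theta(model_spec("orientation_estimation")), engine = "cpp"),
    "compiled path")
})

test_that("log posterior is the likelihood plus a flat sampling-scale prior", {
  m <- model_spec("fixed", fit_scope = "taskA")
  th1 <- fixed_theta(m, 1)
  th2 <- fixed_theta(m, 2)
  d <- generate_dataset(m, th1, small_structure(40, "A"), seed = 6,
                        testing_only = TRUE)
  lp1 <- log_posterior(d, m, th1)
  lp2 <- log_posterior(d, m, th2)
  ll1 <- dataset_log_likelihood(d, m, th1)
  ll2 <- dataset_log_likelihood(d, m, th2)
  expect_equal(lp1 - lp2, ll1 - ll2, tolerance = 1e-10)
  # outside the box: -Inf; just inside: finite
  tab <- param_table(m)
  th_out <- th1
  th_out["ka_4"] <- tab$upper_s[tab$name == "ka_4"] + 1e-6
  expect_identical(log_posterior(d, m, th_out), -Inf)
  th_in <- th1
  th_in["ka_4"] <- tab$upper_s[tab$name == "ka_4"] - 1e-9
  expect_true(is.finite(log_posterior(d, m, th_in)))
})

test_that("orientation-estimation lookup resolution is converged", {
  m <- model_spec("orientation_estimation", fit_scope = "taskB")
  th <- fixed_theta(m, 7)
  d <- generate_dataset(m, th, small_structure(60, "B"), seed = 8,
                        testing_only = TRUE)
  ll_full <- dataset_log_likelihood(d, m, th)
  # halve both lookup resolutions via the internal boundary routine
  tasks <- confobs:::default_tasks("gabor")
  dec <- confobs:::decode_params(m, th, tasks)
  prep <- confobs:::prepare_trials(d, m, NULL)
  tr <- prep$trials
  sig <- sigma_of(dec$noise, tr$reliability_value, tr$orientation_deg)
  ll_at <- function(nx, ns) {
    b <- confobs:::oe_measurement_boundaries(tasks$B, dec$crit$B$k, sig,
                                             n_x = nx, n_sigma = ns)
    p <- confobs:::interval_masses(b, tr$orientation_deg, sig, "B")
    pm <- confobs:::apply_lapses(p, dec$lapses, tr$prev_response)
    sum(log(pm[cbind(seq_len(nrow(tr)), tr$response)]))
  }
  expect_lt(abs(ll_at(500, 50) - ll_at(250, 25)), 0.1)
  expect_equal(ll_at(500, 50), ll_full, tolerance = 1e-10)
  expect_true(is.finite(ll_full))
})
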