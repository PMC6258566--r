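test_that("slice sampler reproduces known targets", {
  set.seed(1)
  out <- slice_sample(function(x) -x^2 / 2, init = 0.3, widths = 1, n = 5e4)
  expect_lt(abs(mean(out$draws)), 0.02)
  expect_lt(abs(var(out$draws) - 1), 0.05)

  # uniform box: support respected, quartile coverage ~25%
  set.seed(2)
  ub <- slice_sample(function(x) if (x[1] < 2 || x[1] > 6) -Inf else 0,
                     init = 3, widths = 1, n = 2e4)
  expect_gte(min(ub$draws), 2)
  expect_lte(max(ub$draws), 6)
  qs <- table(cut(ub$draws, seq(2, 6, by = 1))) / 2e4
  expect_true(all(abs(qs - 0.25) < 0.02))

  # seeded reproducibility
  set.seed(3)
  a <- slice_sample(function(x) -abs(x), 0, 1, 100)
  set.seed(3)
  b <- slice_sample(function(x) -abs(x), 0, 1, 100)
  expect_identical(a, b)
  expect_error(slice_sample(function(x) -Inf, 0, 1, 10), "finite")
})

test_that("slice sampler matches a conjugate Gaussian posterior", {
  # 20 observations, known sd 1, flat prior: posterior N(ybar, 1/20)
  set.seed(4)
  y <- rnorm(20, 1.4, 1)
  lt <- function(mu) -sum((y - mu)^2) / 2
  out <- slice_sample(lt, init = 0, widths = 0.5, n = 2e4)
  draws <- out$draws[-(1:500), ]
  expect_lt(abs(mean(draws) - mean(y)), 0.012)
  expect_lt(abs(sd(draws) - sqrt(1 / 20)), 0.012)
})

test_that("two-parameter posterior agrees with a dense-grid evaluation", {
  # correlated Gaussian target: location and log-scale of 40 observations
  set.seed(5)
  y <- rnorm(40, 2, 1.5)
  sy <- sum(y); syy <- sum(y^2)          # sufficient statistics
  lt <- function(th) {
    mu <- th[1]; ls <- th[2]
    if (abs(mu) > 10 || abs(ls) > 3) return(-Inf)
    -40 * ls - (syy - 2 * mu * sy + 40 * mu^2) / (2 * exp(2 * ls))
  }
  out <- slice_sample(lt, c(0, 0), c(0.5, 0.3), 4e5)
  draws <- out$draws[-(1:2000), ]
  gx <- seq(1.4, 2.6, length.out = 50)
  gy <- seq(log(1), log(2.3), length.out = 50)
  lp <- outer(gx, gy, Vectorize(function(a, b) lt(c(a, b))))
  pg <- exp(lp - max(lp)); pg <- pg / sum(pg)
  h <- table(cut(draws[, 1], c(-Inf, gx[-1] - diff(gx)[1] / 2, Inf)),
             cut(draws[, 2], c(-Inf, gy[-1] - diff(gy)[1] / 2, Inf)))
  ph <- h / sum(h)
  expect_lt(0.5 * sum(abs(ph - pg)), 0.05)   # total-variation distance
})

test_that("chain processing applies burn, thinning and the lp filter", {
  m <- model_spec("fixed", fit_scope = "taskA", response_mode = "choice_only")
  th <- fixed_theta(m)
  d <- generate_dataset(m, th, small_structure(150, "A"), seed = 71,
                        testing_only = TRUE)
  cfg <- chain_config(n_chains = 2, n_samples = 120, keep_per_chain = 30,
                      seed = 5)
  fit <- suppressWarnings(fit_mcmc(d, m, config = cfg,
                                   start_source = "plausible"))
  expect_s3_class(fit, "co_fit")
  # retained counts per chain within 1 of target (before the lp filter,
  # which can only remove draws)
  expect_lte(max(table(fit$draws$chain)), 30)
  expect_lte(max(fit$draws$lp) - min(fit$draws$lp), 40)
  expect_equal(ncol(fit$pointwise), 150)
  expect_equal(rowSums(fit$pointwise),
               fit$draws$lp + sum(log(fit$priors$upper_s -
                                        fit$priors$lower_s)),
               tolerance = 1e-8)
  expect_true(all(c("rhat", "ess") %in% names(fit$diagnostics)))
  td <- tidy(fit)
  expect_equal(td$term, fit$priors$name)
  gl <- glance(fit)
  expect_equal(gl$n_trials, 150)
  # keep larger than available post-burn draws: all kept, flag set
  cfg2 <- chain_config(n_chains = 1, n_samples = 60, keep_per_chain = 1000,
                       seed = 6)
  fit2 <- suppressWarnings(fit_mcmc(d, m, config = cfg2,
                                    start_source = "plausible",
                                    pointwise = FALSE))
  expect_true(any(grepl("kept all", fit2$flags)))
})

test_that("bounded MLE recovers boundaries and beats the generating parameters", {
  m <- model_spec("fixed", fit_scope = "taskA", response_mode = "choice_only")
  tab <- param_table(m)
  th <- fixed_theta(m, 13)
  th["lambda_repeat"] <- 0.01
  d <- generate_dataset(m, th,
                        session_structure(n_sessions = 1, tasks = "A",
                                          category_training = c(0, 0),
                                          confidence_training = c(0, 0),
                                          testing = c(1, 4000)),
                        seed = 81, testing_only = TRUE)
  set.seed(8)
  fit <- fit_mle(d, m, n_restarts = 2, maxit = 300)
  expect_gte(fit$loglik, dataset_log_likelihood(d, m, th) - 1e-6)
  # category boundary recovered within half a degree at 4000 trials
  expect_lt(abs(fit$theta["ka_4"] - th["ka_4"]), 0.5)
  expect_equal(tidy(fit)$term, tab$name)
  expect_s3_class(glance(fit), "tbl_df")
})

test_that("one-parameter MLE matches a dense grid search", {
  # single criterion: fix everything but the Task A category boundary
  m <- model_spec("fixed", fit_scope = "taskA", response_mode = "choice_only")
  th <- fixed_theta(m, 17)
  d <- generate_dataset(m, th, small_structure(600, "A"), seed = 91,
                        testing_only = TRUE)
  tab <- param_table(m)
  bounds <- tab
  eps <- 1e-9
  for (nm in tab$name) {
    if (nm == "ka_4") next
    i <- bounds$name == nm
    bounds$lower_s[i] <- th[nm] - eps
    bounds$upper_s[i] <- th[nm] + eps
  }
  set.seed(9)
  fit <- fit_mle(d, m, bounds = bounds, n_restarts = 2, maxit = 400)
  grid <- seq(-20, 20, length.out = 1e4)
  ll <- vapply(grid, function(k) {
    th2 <- th; th2["ka_4"] <- k
    dataset_log_likelihood(d, m, th2)
  }, numeric(1))
  expect_lt(abs(fit$theta["ka_4"] - grid[which.max(ll)]),
            2 * diff(grid)[1] + 1e-3)
})
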