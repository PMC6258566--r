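tA <- task_spec("A")
tB <- task_spec("B")

test_that("log posterior ratio matches its closed forms", {
  expect_equal(log_posterior_ratio(tA, 0, 3), 0)          # symmetry
  expect_equal(log_posterior_ratio(tA, -5, 5), 0.8)
  expect_equal(log_posterior_ratio(tB, 0, 4), 0.5 * log(160 / 25))
  # unequal priors shift d by the log prior ratio
  tAp <- task_spec("A", prior_c1 = 0.8)
  expect_equal(log_posterior_ratio(tAp, 0, 3), log(0.8 / 0.2))
  # marginal category likelihood: variances add
  expect_equal(category_likelihood(0, 0, 0, 12), 1 / (12 * sqrt(2 * pi)))
  expect_equal(integrate(function(x) category_likelihood(x, 4, -4, 5),
                         -Inf, Inf)$value, 1, tolerance = 1e-6)
})

test_that("probability correct is the logistic of d (|d| for the choice)", {
  expect_equal(prob_correct(0), 0.5)
  expect_equal(prob_correct(0.8), 1 / (1 + exp(-0.8)))
  expect_equal(prob_correct(-0.8, chosen = TRUE), prob_correct(0.8))
  expect_equal(prob_correct(1e6), 1)
})

test_that("bayes boundary inversion agrees with bisection root-finding", {
  set.seed(42)
  for (i in 1:50) {
    sig <- runif(1, 0.5, 15)
    for (task in list(tA, tB)) {
      dmax <- log_posterior_ratio(task, 0, sig)
      k <- if (task$task_id == "B") runif(1, dmax - 6, dmax - 0.01)
           else runif(1, -4, 4)
      b <- drop(bayes_boundaries(task, k, sig))
      f <- function(x) log_posterior_ratio(task, x, sig) - k
      if (task$task_id == "B") {
        root <- abs(uniroot(f, c(0, 200), tol = 1e-12)$root)
      } else {
        root <- uniroot(f, c(-200, 200), tol = 1e-12)$root
      }
      expect_lt(abs(b - root), 1e-9)
    }
  }
})

test_that("Task B criteria above the d maximum collapse to empty regions", {
  dmax <- log_posterior_ratio(tB, 0, 4)
  expect_equal(drop(bayes_boundaries(tB, dmax + 1, 4)), 0)
  expect_equal(drop(bayes_boundaries(tA, 0, c(1, 5, 9))), rep(0, 3))
  expect_error(bayes_boundaries(task_spec("B", sigma_cat = c(5, 5)), 0, 4),
               "undefined")
})

test_that("Task A bayes boundaries are affine in sigma^2", {
  k <- c(-1.2, 0.4, 2)
  sig <- seq(0.5, 20, length.out = 30)
  b <- bayes_boundaries(tA, k, sig)
  for (j in seq_along(k)) {
    fitj <- lm(b[, j] ~ I(sig^2))
    expect_lt(max(abs(resid(fitj))), 1e-9)
    # sorted boundaries pair with reverse-sorted criteria (2 mu_1 < 0)
    expect_equal(unname(coef(fitj)[2]),
                 sort(k, decreasing = TRUE)[j] / (2 * tA$mu[1]),
                 tolerance = 1e-9)
  }
})

test_that("decision-noise grid is a normalized symmetric quadrature", {
  g <- dnoise_grid(0.7)
  expect_length(g$eta, 101)
  expect_equal(sum(g$weight), 1)
  expect_equal(g$weight, rev(g$weight))
  expect_equal(g$eta[51], 0)
  # marginalized Task A choice probability at x = 0 stays 0.5 by symmetry
  m <- model_spec("bayes_weak", d_noise = TRUE, response_mode = "choice_only")
  th <- fixed_theta(m)
  th["ka_4"] <- 0; th["kb_4"] <- 0
  tr <- condition_trials("A", 0, 3)
  p <- core_response_probabilities(tr, m, th)
  expect_equal(p[1, 1], 0.5, tolerance = 1e-9)
})

test_that("heuristic boundaries follow their sigma laws and sort crossings", {
  expect_equal(drop(heuristic_boundaries("quad", 1, 2, 3)), 19)
  expect_equal(heuristic_boundaries("lin", c(-3, 1), c(0, 0), c(2, 5)),
               heuristic_boundaries("fixed", c(-3, 1), sigma = c(2, 5)))
  # crossing boundary functions are re-ordered per sigma, never negative mass
  b <- heuristic_boundaries("lin", c(0, 1), c(2, -2), sigma = c(0, 1, 2))
  expect_true(all(apply(b, 1, diff) >= 0))
  # Task B boundaries clipped at zero
  bB <- heuristic_boundaries("lin", c(-5, 3), c(0, 0), 1, task_id = "B")
  expect_equal(drop(bB), c(0, 3))
  expect_error(heuristic_boundaries("fixed", 1, m = 2, sigma = 1), "slopes")
})

test_that("Task A bayes boundaries are reproduced exactly by Quad in sigma^2", {
  k <- c(-2, -1, 0.5, 1, 1.5, 2.2, 3)
  sig <- c(1, 3, 7, 12)
  bb <- bayes_boundaries(tA, k, sig)
  lpr <- 0
  kq <- (sort(k) - lpr) * tA$sigma_cat[1]^2 / (2 * tA$mu[1])
  mq <- (sort(k) - lpr) / (2 * tA$mu[1])
  bq <- heuristic_boundaries("quad", kq, mq, sig)
  expect_equal(bb, bq, tolerance = 1e-12)
})

test_that("MAP orientation estimates shrink toward the prior modes", {
  expect_equal(map_orientation_estimate(0, 4, tB), 0, tolerance = 1e-6)
  # likelihood dominates as sigma -> 0
  expect_equal(map_orientation_estimate(c(-7, 3), 0.05, tB), c(-7, 3),
               tolerance = 0.01)
  # shrinkage at large sigma, against brute-force grid maximization
  shat <- map_orientation_estimate(5, 10, tB)
  expect_lt(abs(shat), 5)
  sg <- seq(-60, 60, length.out = 1e4)
  brute <- sg[which.max(dnorm(sg, 5, 10) *
                          (dnorm(sg, 0, 3) + dnorm(sg, 0, 12)))]
  expect_lt(abs(shat - brute), 0.05)
})

test_that("linear neural readout moments match the population simulation", {
  mo <- linear_neural_moments(0, 3, a = 0.5, sigma_tc = 20)
  expect_equal(mo$mean, 0)
  expect_equal(mo$var, 0.5 / 9 * sqrt(2 * pi * 400) * 400)
  mo2 <- linear_neural_moments(c(-6, 6), 3, 0.5, 20)
  expect_equal(mo2$mean[1], -mo2$mean[2])
  expect_equal(mo2$var[1], mo2$var[2])
  # Poisson population oracle: neurons at unit spacing (the continuum
  # moment formulas assume unit density and fold the weight scale linearly,
  # so the oracle runs at a = 1 where a and a^2 coincide)
  set.seed(7)
  s <- 5; sigma <- 2; stc <- 15
  pref <- seq(-200, 200, by = 1)
  g <- 1 / sigma^2
  rate <- g * exp(-(s - pref)^2 / (2 * stc^2))
  nrep <- 4000
  z <- vapply(seq_len(nrep), function(i)
    sum(pref * rpois(length(pref), rate)), numeric(1))
  mo3 <- linear_neural_moments(s, sigma, a = 1, sigma_tc = stc)
  expect_lt(abs(mean(z) - mo3$mean), 3 * sd(z) / sqrt(nrep))
  expect_lt(abs(var(z) - mo3$var) / mo3$var, 0.15)
})

test_that("hybrid decision variable mixes precision and probability correct", {
  expect_equal(hybrid_decision_variable(0.8, 2, 0), prob_correct(0.8))
  expect_equal(hybrid_decision_variable(0, 2, 4), 1 + 0.5)
  sig <- seq(0.5, 10, length.out = 40)
  v <- hybrid_decision_variable(1.2, sig, 3)
  expect_true(all(diff(v) < 0))
})
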