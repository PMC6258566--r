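test_that("information criteria follow their formulas", {
  ic <- information_criteria(0, 0, 10)
  expect_equal(ic$aic, 0)
  ic2 <- information_criteria(-100, 5, 1000)
  expect_equal(ic2$aic, 210)
  expect_equal(ic2$bic, 200 + 5 * log(1000))
  expect_equal(ic2$aicc, 210 + 2 * 5 * 6 / (1000 - 6))
  expect_equal(ic2$elpd_aic, -105)
  # BIC exceeds AIC once log t > 2
  for (t in c(8, 50, 4320))
    expect_gt(information_criteria(-10, 3, t)$bic,
              information_criteria(-10, 3, t)$aic)
  expect_true(is.na(information_criteria(-10, 9, 10)$aicc))
})

test_that("WAIC penalizes by the pointwise variance", {
  ll <- matrix(rep(log(c(0.2, 0.5, 0.7)), each = 50), nrow = 50)
  w <- waic(ll)
  expect_equal(w$p_waic, 0)
  expect_equal(w$elpd_waic, sum(log(c(0.2, 0.5, 0.7))))
  expect_error(waic(ll[1, , drop = FALSE]), "2 posterior draws")
  set.seed(1)
  ll2 <- matrix(rnorm(2000, -1, 0.3), nrow = 200)
  expect_lte(waic(ll2)$elpd_waic, waic(ll2)$lppd)
})

test_that("PSIS-LOO matches brute-force exact leave-one-out on a conjugate model", {
  fx <- conjugate_fixture()
  res <- psis_loo(fx$ll)
  expect_lt(abs(res$elpd_loo - fx$exact_loo), 0.3)
  expect_lte(res$elpd_loo, sum(apply(fx$ll, 2, function(v)
    log(mean(exp(v))))) + 1e-10)          # LOO <= lppd
  expect_true(all(res$khat < 0.7))
  # WAIC close to exact LOO too on this well-behaved model
  expect_lt(abs(waic(fx$ll)$elpd_waic - fx$exact_loo), 0.5)
})

test_that("degenerate importance weights reduce LOO to the plain lppd", {
  p <- c(0.3, 0.6, 0.05)
  ll <- matrix(rep(log(p), each = 200), nrow = 200)
  res <- suppressWarnings(psis_loo(ll))
  expect_equal(res$elpd_loo, sum(log(p)))
  expect_error(psis_loo(matrix(c(-1, -Inf, -2, -3), 2)), "non-finite")
})

test_that("pareto tail fit recovers known shapes", {
  set.seed(3)
  for (k in c(0.2, 0.5)) {
    y <- (runif(4000)^(-k) - 1) / k     # GPD(k, sigma = 1)
    fit <- confobs:::gpd_fit_pwm(y)
    expect_lt(abs(fit[1] - k), 0.08)
    expect_lt(abs(fit[2] - 1), 0.1)
  }
})

test_that("bootstrap of summed differences behaves on degenerate and CLT cases", {
  tbl <- tibble::tibble(dataset = rep(c("s1", "s2", "s3"), each = 2),
                        model = rep(c("a", "b"), 3),
                        loo = c(-100, -100, -80, -80, -60, -60))
  set.seed(4)
  b0 <- bootstrap_summed_differences(tbl, n_boot = 500)
  expect_equal(b0$median, c(0, 0))
  expect_equal(b0$lower, b0$upper)
  # singleton dataset: CI collapses to the single difference
  tbl1 <- tibble::tibble(dataset = "s1", model = c("a", "b"),
                         loo = c(-93, -100))
  b1 <- bootstrap_summed_differences(tbl1, reference_model = "a",
                                     n_boot = 200)
  expect_equal(b1$median[b1$model == "b"], 7)
  expect_equal(b1$lower[b1$model == "b"], 7)
  expect_equal(b1$upper[b1$model == "b"], 7)
  # CLT check: 11 differences ~ N(200, 50)
  set.seed(5)
  diffs <- rnorm(11, 200, 50)
  tbl2 <- tibble::tibble(dataset = rep(paste0("s", 1:11), each = 2),
                         model = rep(c("ref", "worse"), 11),
                         loo = c(rbind(rep(0, 11), -diffs)))
  b2 <- bootstrap_summed_differences(tbl2, reference_model = "ref",
                                     n_boot = 1e4)
  se <- sd(diffs) * sqrt(11)
  expect_lt(abs(b2$median[b2$model == "worse"] - sum(diffs)), 3 * se)
  expect_error(bootstrap_summed_differences(tbl[-1, ]), "missing scores")
})

test_that("metric agreement is a Spearman correlation with the expected fixed points", {
  set.seed(6)
  tbl <- tibble::tibble(dataset = rep("s1", 5),
                        model = paste0("m", 1:5),
                        elpd_aic = c(-10, -14, -8, -22, -16))
  tbl$same <- tbl$elpd_aic
  tbl$neg <- -tbl$elpd_aic
  ma <- metric_agreement(tbl, metrics = c("elpd_aic", "same", "neg"))
  expect_equal(ma$rho[ma$metric1 == "elpd_aic" & ma$metric2 == "same"], 1)
  expect_equal(ma$rho[ma$metric1 == "elpd_aic" & ma$metric2 == "neg"], -1)
  # AIC vs BIC at shared (n, t): monotone transform, rho = 1
  ll <- c(-500, -620, -480, -710, -555)
  ics <- information_criteria(ll[1], 5, 1000)
  tbl2 <- dplyr::bind_rows(lapply(ll, information_criteria, n_params = 5,
                                  n_trials = 1000))
  tbl2$dataset <- "s1"; tbl2$model <- paste0("m", 1:5)
  ma2 <- metric_agreement(tbl2, metrics = c("elpd_aic", "elpd_bic"))
  expect_equal(ma2$rho, 1)
})

test_that("single-candidate recovery trivially selects the generator", {
  ms <- list(fixed = model_spec("fixed", fit_scope = "taskA",
                                response_mode = "choice_only"))
  rec <- run_model_recovery(ms, n_datasets_per_model = 2,
                            structure = small_structure(200, "A"),
                            seed = 7, n_restarts = 1, maxit = 60)
  expect_equal(rec$selection_rate, 1)
  expect_equal(dim(rec$delta_aic), c(1, 1))
  expect_equal(rec$delta_aic[1, 1], 0)
  td <- tidy(rec)
  expect_true(all(td$row_best))
})

test_that("strong-signal recovery separates Fixed from Lin on every dataset", {
  ms <- list(fixed = model_spec("fixed", fit_scope = "taskA",
                                response_mode = "choice_only"),
             lin = model_spec("lin", fit_scope = "taskA",
                              response_mode = "choice_only"))
  src <- function(model) {
    th <- draw_params(model, 1, "plausible")[1, ]
    if (model$family == "lin") th["ma_4"] <- 1  # strong sigma dependence
    th
  }
  big <- session_structure(n_sessions = 1, tasks = "A",
                           category_training = c(0, 0),
                           confidence_training = c(0, 0),
                           testing = c(3, 1440))
  rec <- run_model_recovery(ms, n_datasets_per_model = 2, structure = big,
                            parameter_source = src, seed = 8,
                            n_restarts = 2, maxit = 150)
  lin_rows <- dplyr::filter(rec$details, generator == "lin")
  win <- dplyr::summarize(lin_rows, w = fitter[which.min(aic)],
                          .by = "replicate")
  expect_true(all(win$w == "lin"))
  expect_equal(rec$delta_aic["lin", "lin"], 0)
})

test_that("bootstrap interval estimates converge as the subject count grows", {
  # repeated subsampling at each subject count: the spread of the
  # bootstrapped interval width across subsamples must shrink steadily
  # toward the full-sample value (a percentile bootstrap of 2 datasets is
  # nearly degenerate, so the mean width itself only stabilizes from
  # moderate counts onward)
  set.seed(11)
  diffs <- rnorm(11, 150, 60)
  width_at <- function(n_subj, n_rep = 60) {
    w <- replicate(n_rep, {
      sub <- sample(diffs, n_subj, replace = TRUE)
      tbl <- tibble::tibble(dataset = rep(paste0("s", seq_len(n_subj)),
                                          each = 2),
                            model = rep(c("ref", "m"), n_subj),
                            loo = c(rbind(rep(0, n_subj), -sub)))
      b <- bootstrap_summed_differences(tbl, reference_model = "ref",
                                        n_boot = 400)
      (b$upper[b$model == "m"] - b$lower[b$model == "m"]) / n_subj
    })
    c(mean = mean(w), sd = sd(w))
  }
  ns <- c(2, 5, 8, 11)
  w <- vapply(ns, width_at, numeric(2))
  expect_true(all(diff(w["sd", ]) < 0))        # convergence of the estimate
  expect_true(all(diff(w["mean", -1]) < 0))    # width shrinks from n >= 5
})

test_that("model specifications round-trip through JSON", {
  m <- model_spec("bayes_weak", d_noise = TRUE, fit_scope = "taskB")
  path <- tempfile(fileext = ".json")
  write_model_spec(m, path)
  m2 <- read_model_spec(path)
  expect_equal(m2, m)
  bad <- jsonlite::read_json(path, simplifyVector = TRUE)
  bad$family <- "fixed"
  jsonlite::write_json(bad, path, auto_unbox = TRUE)
  expect_error(read_model_spec(path), "d_noise")
})
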