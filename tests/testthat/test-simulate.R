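test_that("generated datasets match the session-structure arithmetic", {
  m <- model_spec("fixed")
  th <- fixed_theta(m)
  d <- generate_dataset(m, th, session_structure(), seed = 11)
  counts <- dplyr::count(tibble::as_tibble(d), phase)
  expect_equal(counts$n[counts$phase == "testing"], 4320)
  expect_equal(counts$n[counts$phase == "category_training"], 2880)
  expect_equal(counts$n[counts$phase == "confidence_training"], 240)
  # responses decompose consistently on every testing trial
  te <- d[d$phase == "testing", ]
  expect_true(all(te$response %in% 1:8))
  rc <- response_to_choice(te$response)
  expect_equal(rc$chosen_category, te$chosen_category)
  expect_equal(rc$confidence, te$confidence)
  expect_equal(choice_to_response(te$chosen_category, te$confidence),
               te$response)
  # reliability levels uniform over 6 levels (chi-square well within range)
  tb <- table(te$reliability_level)
  expect_length(tb, 6)
  expect_lt(max(abs(tb / sum(tb) - 1 / 6)), 4 * sqrt(1 / 6 * 5 / 6 / 4320))
  # categories equiprobable
  expect_lt(abs(mean(te$true_category == 1) - 0.5), 4 * 0.5 / sqrt(4320))
})

test_that("identical seeds give identical datasets, bitwise on the CSV", {
  m <- model_spec("quad")
  th <- fixed_theta(m)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_dataset(generate_dataset(m, th, small_structure(40), seed = 21), f1)
  write_dataset(generate_dataset(m, th, small_structure(40), seed = 21), f2)
  expect_identical(readLines(f1), readLines(f2))
  d3 <- generate_dataset(m, th, small_structure(40), seed = 22)
  write_dataset(d3, f2)
  expect_false(identical(readLines(f1), readLines(f2)))
  # round trip preserves the trials and provenance
  back <- read_dataset(f2)
  expect_equal(as.data.frame(back)[names(back) != "subject_id"],
               as.data.frame(d3)[names(back) != "subject_id"],
               tolerance = 1e-12)
  expect_equal(attr(back, "provenance")$model, "quad")
  expect_equal(attr(back, "provenance")$seed, 22)
})

test_that("full lapses pull confidence toward the low endpoint", {
  # with endpoint weights (1, 0), the interpolated full-lapse confidence
  # distribution is (1, 2/3, 1/3, 0)/2 over levels 1..4: the very-low level
  # dominates and very-high confidence never occurs in a full lapse
  p <- apply_lapses(rep(1 / 8, 8),
                    list(lambda_full = 1, lambda_1 = 1, lambda_4 = 0,
                         lambda_conf = 0, lambda_repeat = 0))
  w <- c(1, 2 / 3, 1 / 3, 0) / 2
  expect_equal(p, 0.5 * w[c(4, 3, 2, 1, 1, 2, 3, 4)])
  expect_equal(sum(p), 1)
  m <- model_spec("fixed")
  th <- fixed_theta(m)
  th["lambda_conf"] <- 0; th["lambda_repeat"] <- 0
  th["lambda_1"] <- 1; th["lambda_4"] <- 0
  th0 <- th; th0["lambda_full"] <- 0
  th["lambda_full"] <- 0.3  # prior box caps the full-lapse rate
  d1 <- generate_dataset(m, th, small_structure(800), seed = 31,
                         testing_only = TRUE)
  d0 <- generate_dataset(m, th0, small_structure(800), seed = 31,
                         testing_only = TRUE)
  expect_gt(mean(d1$confidence == 1), mean(d0$confidence == 1) + 0.05)
})

test_that("zero-noise sign rule recovers the design accuracy in Task A", {
  m <- model_spec("fixed", fit_scope = "taskA")
  tab <- param_table(m)
  th <- fixed_theta(m)
  th[c("sigma_low", "sigma_high")] <- log(0.1)  # lowest allowed noise
  th["psi"] <- 0
  th["beta"] <- tab$lower_s[tab$name == "beta"]
  th[paste0("ka_", 1:7)] <- c(-30, -20, -10, 0, 10, 20, 30)
  th[c("lambda_full", "lambda_conf", "lambda_repeat")] <- 0
  big <- session_structure(n_sessions = 1, tasks = "A",
                           category_training = c(0, 0),
                           confidence_training = c(0, 0),
                           testing = c(1, 2e4))
  d <- generate_dataset(m, th, big, seed = 41, testing_only = TRUE)
  acc <- mean(d$chosen_category == d$true_category)
  expect_lt(abs(acc - pnorm(0.8)), 4 * sqrt(0.79 * 0.21 / 2e4) + 0.005)
})

test_that("simulated frequencies match analytic probabilities through generate_dataset", {
  # joint oracle of the simulator and the likelihood on a binned grid
  m <- model_spec("bayes_weak")
  th <- fixed_theta(m, seed = 55)
  th["lambda_repeat"] <- 0
  big <- session_structure(n_sessions = 1, tasks = c("A", "B"),
                           category_training = c(0, 0),
                           confidence_training = c(0, 0),
                           testing = c(1, 3e4))
  d <- generate_dataset(m, th, big, seed = 51, testing_only = TRUE)
  d <- d[d$phase == "testing", ]
  probs <- core_response_probabilities(d, m, th)
  dec <- confobs:::decode_params(m, th, attr(d, "tasks"))
  probs <- apply_lapses(probs, dec$lapses)
  # aggregate per (task, reliability, coarse stimulus bin)
  bin <- cut(d$orientation_deg, c(-Inf, -8, -3, 0, 3, 8, Inf))
  cell <- interaction(d$task, d$reliability_level, bin, drop = TRUE)
  okc <- 0; nc <- 0
  for (cl in levels(cell)) {
    i <- which(cell == cl)
    if (length(i) < 400) next
    emp <- tabulate(d$response[i], 8) / length(i)
    p <- colMeans(probs[i, , drop = FALSE])
    se <- sqrt(pmax(p * (1 - p), 1e-12) / length(i))
    okc <- okc + sum(abs(emp - p) <= 4 * se + 1e-12)
    nc <- nc + 8
  }
  expect_gt(nc, 100)
  expect_gte(okc / nc, 0.95)
})

test_that("re-simulated responses keep the stimuli fixed", {
  m <- model_spec("quad")
  th <- fixed_theta(m)
  d <- generate_dataset(m, th, small_structure(60), seed = 61)
  d2 <- simulate_responses(d, m, th, seed = 62)
  expect_equal(d2$orientation_deg, d$orientation_deg)
  expect_equal(d2$true_category, d$true_category)
  expect_equal(d2$reliability_level, d$reliability_level)
  te <- d2$phase == "testing"
  expect_true(all(d2$response[te] %in% 1:8))
  expect_false(identical(d2$response[te], d$response[te]))
  # training rows untouched
  expect_equal(d2$chosen_category[!te], d$chosen_category[!te])
})

test_that("invalid parameter vectors are rejected with the offending names", {
  m <- model_spec("quad")
  th <- fixed_theta(m)
  expect_error(generate_dataset(m, th[-1], small_structure(10), seed = 1),
               "sigma_low")
  th_bad <- th
  th_bad["lambda_full"] <- 2
  expect_error(generate_dataset(m, th_bad, small_structure(10), seed = 1),
               "lambda_full")
})

test_that("noiseless ideal-observer accuracies hit the ~80% design target", {
  accA <- ideal_observer_accuracy(task_spec("A"))
  accB <- ideal_observer_accuracy(task_spec("B"))
  expect_equal(accA, pnorm(0.8))
  s1 <- 3; s2 <- 12
  sstar <- sqrt(2 * log(s2 / s1) / (1 / s1^2 - 1 / s2^2))
  expect_equal(accB, 0.5 * ((2 * pnorm(sstar / s1) - 1) +
                              2 * pnorm(-sstar / s2)))
  simA <- ideal_observer_accuracy(task_spec("A"), "simulate", n = 2e5,
                                  seed = 3)
  expect_lt(abs(simA - accA), 4 * sqrt(0.21 * 0.79 / 2e5))
})
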