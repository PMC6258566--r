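#' Task specification for the two orientation-categorization tasks
#'
#' Task A is a mean-discrimination task: the two categories draw orientations
#' from Gaussians with means -4 and +4 degrees and a common 5-degree s.d.
#' Task B is a spread-discrimination task: both categories are centred on 0
#' degrees, with s.d. 3 (category 1, narrow) versus 12 (category 2, wide)
#' degrees. Category means and spreads were chosen so that a noiseless optimal
#' observer is correct on roughly 80% of trials in either task.
#'
#' Orientations are in degrees, 0 = horizontal, positive = rightward tilt;
#' category 1 is the leftward (Task A) or narrow (Task B) category.
#'
#' @param task_id `"A"` or `"B"`.
#' @param stimulus `"gabor"` (reliability = contrast) or `"ellipse"`
#'   (reliability = eccentricity); selects the preset physical reliability
#'   values for the six reliability levels.
#' @param prior_c1 Prior probability of category 1 (design value 0.5).
#' @param mu,sigma_cat Optional overrides of the category means / s.d.s
#'   (length-2 numeric, category 1 then category 2). Defaults are the task's
#'   design values.
#' @param reliability_values Optional override of the six physical reliability
#'   values (strictly increasing).
#'
#' @return An object of class `co_task`: a list with fields `task_id`, `mu`,
#'   `sigma_cat`, `reliability_values`, `prior_c1`.
#' @examples
#' task_spec("A")
#' task_spec("B", stimulus = "ellipse")
#' @export
task_spec <- function(task_id = c("A", "B"), stimulus = c("gabor", "ellipse"),
                      prior_c1 = 0.5, mu = NULL, sigma_cat = NULL,
                      reliability_values = NULL) {
  task_id <- match.arg(task_id)
  stimulus <- match.arg(stimulus)
  if (is.null(mu)) mu <- if (task_id == "A") c(-4, 4) else c(0, 0)
  if (is.null(sigma_cat)) sigma_cat <- if (task_id == "A") c(5, 5) else c(3, 12)
  if (is.null(reliability_values)) {
    reliability_values <- reliability_preset(stimulus)
  }
  stopifnot(length(mu) == 2, length(sigma_cat) == 2, all(sigma_cat >= 0),
            length(reliability_values) == 6,
            all(diff(reliability_values) > 0),
            prior_c1 > 0, prior_c1 < 1)
  structure(
    list(task_id = task_id, stimulus = stimulus, mu = as.numeric(mu),
         sigma_cat = as.numeric(sigma_cat),
         reliability_values = as.numeric(reliability_values),
         prior_c1 = prior_c1),
    class = "co_task")
}

#' @export
print.co_task <- function(x, ...) {
  cat(sprintf("<co_task %s> mu = (%g, %g), sigma_cat = (%g, %g), prior_c1 = %g\n",
              x$task_id, x$mu[1], x$mu[2], x$sigma_cat[1], x$sigma_cat[2],
              x$prior_c1))
  cat("  reliability:", paste(signif(x$reliability_values, 3), collapse = ", "),
      sprintf(" (%s)\n", x$stimulus))
  invisible(x)
}

#' Preset physical reliability values
#'
#' Six Gabor contrasts (0.004, 0.008, 0.017, 0.033, 0.067, 0.135) or six
#' ellipse eccentricities (0.15, 0.28, 0.41, 0.54, 0.67, 0.8), ordered from
#' least to most reliable.
#'
#' @param stimulus `"gabor"` or `"ellipse"`.
#' @return Numeric vector of length 6, strictly increasing.
#' @export
reliability_preset <- function(stimulus = c("gabor", "ellipse")) {
  stimulus <- match.arg(stimulus)
  switch(stimulus,
         gabor = c(0.004, 0.008, 0.017, 0.033, 0.067, 0.135),
         ellipse = c(0.15, 0.28, 0.41, 0.54, 0.67, 0.80))
}

#' Session structure of an experiment
#'
#' Describes how many sessions a subject completes, which tasks appear in each
#' session, and the block structure of the three phases: category training
#' (choice only, full stimulus strength, with feedback), confidence training
#' (introduces the 8-button category + confidence response), and testing (the
#' analyzed trials). The default is the structure of experiment 1: 5 sessions,
#' both tasks per session, 3 blocks x 96 category-training trials, 1 block x
#' 24 confidence-training trials and 3 blocks x 144 testing trials per task
#' per session, i.e. 2880 / 240 / 4320 trials per subject.
#'
#' @param n_sessions Number of sessions.
#' @param tasks Character vector of task ids done in each session.
#' @param category_training,confidence_training,testing Length-2 integer
#'   vectors `c(blocks, trials_per_block)` per task per session.
#' @return An object of class `co_session`.
#' @examples
#' structure_counts(session_structure())
#' @export
session_structure <- function(n_sessions = 5, tasks = c("A", "B"),
                              category_training = c(3, 96),
                              confidence_training = c(1, 24),
                              testing = c(3, 144)) {
  chk <- function(x, nm) {
    if (length(x) != 2 || any(x < 0) || any(x != round(x)))
      stop(nm, " must be c(blocks, trials_per_block), non-negative integers",
           call. = FALSE)
    as.integer(x)
  }
  stopifnot(n_sessions >= 1, n_sessions == round(n_sessions),
            length(tasks) >= 1, all(tasks %in% c("A", "B")))
  structure(
    list(n_sessions = as.integer(n_sessions), tasks = tasks,
         category_training = chk(category_training, "category_training"),
         confidence_training = chk(confidence_training, "confidence_training"),
         testing = chk(testing, "testing")),
    class = "co_session")
}

#' Experiment presets
#'
#' `"exp1"` is the full experiment-1 structure (both tasks, 4320 testing
#' trials). `"exp2"` keeps both tasks but reaches 3240 testing trials
#' (3 blocks x 108 per task per session); `"exp3"` is Task B only with 3240
#' testing trials (3 blocks x 216 per session). The per-block arithmetic of
#' experiments 2-3 is configurable via [session_structure()].
#'
#' @param preset One of `"exp1"`, `"exp2"`, `"exp3"`.
#' @return A list with elements `structure` (a `co_session`) and `tasks`
#'   (character vector of task ids).
#' @export
experiment_preset <- function(preset = c("exp1", "exp2", "exp3")) {
  preset <- match.arg(preset)
  switch(preset,
    exp1 = list(structure = session_structure(), tasks = c("A", "B")),
    exp2 = list(structure = session_structure(testing = c(3, 108)),
                tasks = c("A", "B")),
    exp3 = list(structure = session_structure(tasks = "B",
                                              testing = c(3, 216)),
                tasks = "B"))
}

#' Closed-form trial counts per phase
#'
#' @param structure A [session_structure()].
#' @return A tibble with columns `phase` and `n_trials` giving the total
#'   per-subject trial count of each phase across all sessions and tasks.
#' @examples
#' structure_counts(session_structure())  # 2880 / 240 / 4320
#' @export
structure_counts <- function(structure) {
  stopifnot(inherits(structure, "co_session"))
  per_part <- structure$n_sessions * length(structure$tasks)
  tibble::tibble(
    phase = c("category_training", "confidence_training", "testing"),
    n_trials = per_part * c(prod(structure$category_training),
                            prod(structure$confidence_training),
                            prod(structure$testing)))
}

#' Convert between response codes and (category, confidence)
#'
#' Responses 1-8 encode category and confidence in a single button press:
#' responses 1-4 are category 1 with confidence 4 ("very high") down to 1
#' ("very low"); responses 5-8 are category 2 with confidence 1 up to 4.
#'
#' @param response Integer vector in 1..8.
#' @param category,confidence Integer vectors ({1,2} and 1..4).
#' @return `response_to_choice()` returns a tibble with columns
#'   `chosen_category` and `confidence`; `choice_to_response()` the integer
#'   response codes.
#' @examples
#' response_to_choice(1:8)
#' choice_to_response(c(1, 2), c(4, 4))  # 1 and 8
#' @export
response_to_choice <- function(response) {
  stopifnot(all(response %in% 1:8))
  cat <- ifelse(response <= 4, 1L, 2L)
  conf <- ifelse(response <= 4, 5L - as.integer(response),
                 as.integer(response) - 4L)
  tibble::tibble(chosen_category = cat, confidence = conf)
}

#' @rdname response_to_choice
#' @export
choice_to_response <- function(category, confidence) {
  stopifnot(all(category %in% 1:2), all(confidence %in% 1:4))
  ifelse(category == 1, 5L - as.integer(confidence),
         4L + as.integer(confidence))
}
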