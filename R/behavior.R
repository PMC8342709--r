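#' Simulate memory-guided saccade behavior
#'
#' Generates per-trial behavioral records from a trial design and a
#' trial-wise neural bias. The signed memory error (saccade endpoint polar
#' angle minus target, wrapped) is
#' `coupling * neural_bias + attract_bias * sign(toward distractor) +
#' Gaussian(0, motor_sd)`; distractor-absent trials receive no attraction
#' term. Response times are log-normal; distractor-present trials are
#' noisier and slower by default, emulating the behavioral cost of
#' attending the distractor.
#'
#' @param design Trial tibble ([generate_design()]).
#' @param neural_bias Trial-wise neural bias, degrees; scalar or per trial.
#' @param coupling Scalar weight linking neural bias to memory error.
#' @param attract_bias Mean attraction toward the distractor, degrees.
#' @param motor_sd SD of motor noise on distractor-absent trials, degrees.
#' @param present_sd_scale Multiplier on `motor_sd` for distractor-present
#'   trials (default 1.25).
#' @param rt_meanlog,rt_sdlog Log-normal RT parameters (log milliseconds).
#' @param rt_present_shift Additive RT cost on present trials, ms.
#' @param seed Integer seed.
#' @return A tibble with `participant_id`, `run_id`, `trial_id`,
#'   `condition`, `memory_error` (signed degrees in (-180, 180\]),
#'   `saccade_endpoint_angle`, `rt_ms`, `excluded`, `exclude_reason`.
#' @export
simulate_behavior <- function(design, neural_bias = 0, coupling = 0,
                              attract_bias = 1, motor_sd = 2,
                              present_sd_scale = 1.25,
                              rt_meanlog = log(350), rt_sdlog = 0.25,
                              rt_present_shift = 40, seed = NULL) {
  if (motor_sd < 0) stop("`motor_sd` must be non-negative")
  n <- nrow(design)
  if (length(neural_bias) == 1) neural_bias <- rep(neural_bias, n)
  if (length(neural_bias) != n) {
    stop("`neural_bias` must be a scalar or one value per trial")
  }
  if (!is.null(seed)) set.seed(seed)

  present <- design$condition == "distractor_present"
  toward <- ifelse(present,
                   sign(wrap_angle(design$relative_distractor_angle)), 0)
  sd_trial <- motor_sd * ifelse(present, present_sd_scale, 1)
  err <- wrap_angle(coupling * neural_bias + attract_bias * toward +
                      stats::rnorm(n, 0, sd_trial))
  rt <- stats::rlnorm(n, rt_meanlog, rt_sdlog) +
    ifelse(present, rt_present_shift, 0)

  tibble::tibble(
    participant_id = design$participant_id,
    run_id = design$run_id,
    trial_id = design$trial_id,
    condition = design$condition,
    memory_error = err,
    saccade_endpoint_angle = angle_mod360(design$target_angle + err),
    rt_ms = rt,
    excluded = FALSE,
    exclude_reason = NA_character_
  )
}

#' Simulate a three-down/one-up adaptive staircase
#'
#' Drives a stimulus-difficulty parameter (e.g., motion coherence) against
#' an observer with a monotone psychometric function: three consecutive
#' correct responses step the coherence down (harder), any error steps it
#' up (easier). The converged proportion correct of this rule is the fixed
#' point of `P(correct)^3 = 0.5`, i.e. about 79.4% for a smooth observer —
#' the "about 80%" operating point of adaptive mapping tasks.
#'
#' @param psychometric Function mapping coherence in \[`floor`, `ceiling`\]
#'   to P(correct); must be monotone non-decreasing.
#' @param n_trials Number of trials (default 10000).
#' @param step Step size in coherence units.
#' @param start Starting coherence.
#' @param floor,ceiling Coherence bounds.
#' @param burn_in Fraction of initial trials discarded before computing the
#'   converged accuracy (default 0.25).
#' @param seed Integer seed.
#' @return A list of class `staircase_result`: `trace` (tibble with
#'   `trial`, `coherence`, `correct`), `accuracy` (post-burn-in proportion
#'   correct), `burn_in`, and `fixed_point` (the analytic 0.5^(1/3)).
#' @examples
#' psy <- function(c) 0.5 + 0.5 * (1 - exp(-(c / 0.5)^3))
#' sc <- simulate_staircase(psy, n_trials = 2000, seed = 1)
#' sc$accuracy
#' @export
simulate_staircase <- function(psychometric, n_trials = 10000, step = 0.02,
                               start = 0.7, floor = 0.001, ceiling = 1,
                               burn_in = 0.25, seed = NULL) {
  stopifnot(is.function(psychometric), n_trials >= 8)
  grid <- seq(floor, ceiling, length.out = 50)
  pg <- vapply(grid, psychometric, numeric(1))
  if (any(diff(pg) < -1e-8)) {
    stop("`psychometric` must be monotone non-decreasing in coherence")
  }
  if (any(pg < 0 | pg > 1)) stop("`psychometric` must return probabilities")
  if (!is.null(seed)) set.seed(seed)

  coh <- numeric(n_trials)
  correct <- logical(n_trials)
  c_now <- start
  streak <- 0L
  for (i in seq_len(n_trials)) {
    coh[i] <- c_now
    correct[i] <- stats::runif(1) < psychometric(c_now)
    if (correct[i]) {
      streak <- streak + 1L
      if (streak == 3L) {
        c_now <- max(c_now - step, floor)
        streak <- 0L
      }
    } else {
      c_now <- min(c_now + step, ceiling)
      streak <- 0L
    }
  }
  keep <- seq.int(base::floor(burn_in * n_trials) + 1L, n_trials)
  structure(
    list(
      trace = tibble::tibble(trial = seq_len(n_trials), coherence = coh,
                             correct = correct),
      accuracy = mean(correct[keep]),
      burn_in = burn_in,
      fixed_point = 0.5^(1 / 3)
    ),
    class = "staircase_result"
  )
}

#' @export
print.staircase_result <- function(x, ...) {
  cat(sprintf(
    "<staircase_result> %d trials, post-burn-in accuracy %.3f (3-down/1-up fixed point %.3f)\n",
    nrow(x$trace), x$accuracy, x$fixed_point
  ))
  invisible(x)
}
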