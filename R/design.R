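#' Default distractor-bin centers
#'
#' The distractor can appear in one of seven bins of relative polar angle
#' (distractor minus memory target). Bins are parameterised by their absolute
#' angular separation from the target; the sign (clockwise vs
#' counterclockwise) is randomised trial-by-trial, and a uniform jitter of
#' up to ±12 degrees is added, so each bin is 24 degrees wide. The default
#' centers 0, 30, ..., 180 tile the circle evenly; their cosines sum to
#' zero, which is what makes distractor representations average out of
#' target-aligned reconstructions.
#'
#' @return Numeric vector of 7 bin centers (absolute separation, degrees).
#' @export
default_bin_centers <- function() seq(0, 180, by = 30)

# canonical within-trial event times, seconds relative to delay onset,
# all on the 750 ms TR grid: pre-cue, target flash, delay start, distractor
# onset (present trials), response cue at end of the 12 s delay
trial_event_times <- function() {
  c(cue = -2.25, target = -0.75, delay = 0, distractor = 4.5, response = 12)
}

#' Generate a counterbalanced memory-guided saccade trial design
#'
#' Builds the experimental session design: each run holds ten trials, seven
#' distractor-present and three distractor-absent in random order, with the
#' seven relative distractor bins counterbalanced exactly once per run.
#' Target polar angles are i.i.d. uniform on \[0, 360); distractor angles sit
#' at the bin's separation from the target, with random sign and uniform
#' ±`jitter` jitter. Event onsets are fixed on the 750 ms TR grid.
#'
#' @param n_runs Number of runs per participant (>= 1).
#' @param n_participants Number of participants (>= 1).
#' @param seed Integer seed; identical seeds give identical tables.
#' @param bin_centers Seven distinct absolute separations, degrees.
#' @param jitter Half-width of the uniform jitter, degrees (default 12).
#' @return A tibble with one row per trial: `participant_id`, `run_id`,
#'   `trial_id`, `condition` (`"distractor_present"`/`"distractor_absent"`),
#'   `target_angle`, `distractor_angle`, `distractor_bin`,
#'   `relative_distractor_angle` (signed, wrapped to (-180, 180\]), and event
#'   onset columns `t_cue`, `t_target`, `t_delay`, `t_distractor`,
#'   `t_response` (seconds relative to delay onset).
#' @examples
#' d <- generate_design(n_runs = 2, seed = 1)
#' mean(d$condition == "distractor_present")
#' @export
generate_design <- function(n_runs, n_participants = 1, seed = NULL,
                            bin_centers = default_bin_centers(),
                            jitter = 12) {
  stopifnot(is.numeric(n_runs), length(n_runs) == 1)
  if (n_runs < 1 || n_participants < 1) {
    stop("`n_runs` and `n_participants` must be positive counts")
  }
  if (length(bin_centers) != 7 || anyDuplicated(bin_centers)) {
    stop("`bin_centers` must be exactly 7 distinct values")
  }
  if (!is.null(seed)) set.seed(seed)

  ev <- trial_event_times()
  one_run <- function(pid, run) {
    condition <- sample(rep(c("distractor_present", "distractor_absent"),
                            c(7L, 3L)))
    bins <- rep(NA_integer_, 10L)
    bins[condition == "distractor_present"] <- sample.int(7L)
    target <- stats::runif(10L, 0, 360)
    sgn <- sample(c(-1, 1), 10L, replace = TRUE)
    jit <- stats::runif(10L, -jitter, jitter)
    rel <- ifelse(is.na(bins), NA_real_,
                  wrap_angle(sgn * (bin_centers[bins] + jit)))
    tibble::tibble(
      participant_id = pid,
      run_id = run,
      trial_id = seq_len(10L),
      condition = condition,
      target_angle = target,
      distractor_angle = angle_mod360(target + rel),
      distractor_bin = bins,
      relative_distractor_angle = rel,
      t_cue = ev[["cue"]], t_target = ev[["target"]],
      t_delay = ev[["delay"]],
      t_distractor = ifelse(is.na(bins), NA_real_, ev[["distractor"]]),
      t_response = ev[["response"]]
    )
  }

  grid <- tidyr::expand_grid(
    participant_id = sprintf("p%02d", seq_len(n_participants)),
    run_id = seq_len(n_runs)
  )
  out <- purrr::pmap(grid, function(participant_id, run_id) {
    one_run(participant_id, run_id)
  })
  dplyr::bind_rows(out) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(trial_id = dplyr::row_number()) |>
    dplyr::ungroup()
}

#' Generate the independent model-estimation design
#'
#' The encoding model is trained on a separate memory-guided saccade task
#' with no distractors: 16 targets evenly spaced around the circle per run
#' (22.5 degrees apart), with the grid staggered by half the spacing on
#' every other run, so two consecutive runs sample 32 unique positions.
#'
#' @param n_runs Number of training runs (>= 2 to cover both grids).
#' @param n_participants Number of participants.
#' @param seed Integer seed (controls only the within-run trial order).
#' @return A tibble like [generate_design()] but with all trials
#'   `distractor_absent` and `distractor_*` columns `NA`.
#' @examples
#' tr <- generate_training_design(n_runs = 2, seed = 1)
#' length(unique(tr$target_angle))
#' @export
generate_training_design <- function(n_runs, n_participants = 1, seed = NULL) {
  if (n_runs < 1) stop("`n_runs` must be a positive count")
  if (n_runs < 2) {
    warning("with `n_runs` = 1 only 16 of the 32 staggered positions appear")
  }
  if (!is.null(seed)) set.seed(seed)
  ev <- trial_event_times()
  spacing <- 360 / 16

  one_run <- function(pid, run) {
    offset <- if (run %% 2 == 1) 0 else spacing / 2
    target <- sample(seq(0, 360 - spacing, by = spacing) + offset)
    tibble::tibble(
      participant_id = pid,
      run_id = run,
      trial_id = seq_len(16L),
      condition = "distractor_absent",
      target_angle = target,
      distractor_angle = NA_real_,
      distractor_bin = NA_integer_,
      relative_distractor_angle = NA_real_,
      t_cue = ev[["cue"]], t_target = ev[["target"]],
      t_delay = ev[["delay"]], t_distractor = NA_real_,
      t_response = ev[["response"]]
    )
  }

  grid <- tidyr::expand_grid(
    participant_id = sprintf("p%02d", seq_len(n_participants)),
    run_id = seq_len(n_runs)
  )
  dplyr::bind_rows(purrr::pmap(grid, function(participant_id, run_id) {
    one_run(participant_id, run_id)
  })) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(trial_id = dplyr::row_number()) |>
    dplyr::ungroup()
}

#' Select trials with the distractor near the memory target
#'
#' Restricts a trial table to distractor-present trials whose absolute
#' relative distractor angle is at most `threshold` degrees (inclusive at
#' the boundary). These are the trials on which attraction of memory toward
#' the distractor aligns with the modeled polar-angle dimension.
#'
#' @param trials Trial tibble from [generate_design()].
#' @param threshold Inclusion threshold, degrees (default 12).
#' @return The qualifying subset of `trials` (possibly empty).
#' @export
near_distractor_select <- function(trials, threshold = 12) {
  dplyr::filter(
    trials,
    .data$condition == "distractor_present",
    abs(wrap_angle(.data$relative_distractor_angle)) <= threshold
  )
}
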