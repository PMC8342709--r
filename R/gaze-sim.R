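#' Simulate 500 Hz gaze traces for scored trials
#'
#' For each trial: fixation at the screen center through the delay, then a
#' memory-guided saccade (minimum-jerk trajectory, main-sequence duration)
#' launched `rt_ms` after the response cue toward the recorded endpoint at
#' the target eccentricity, followed by stable fixation at the endpoint.
#' Optional blinks drop contiguous samples to `NA`, and white positional
#' jitter can be added. Ground-truth saccade onsets/offsets are returned
#' alongside the trace.
#'
#' @param design Trial tibble ([generate_design()]), one participant.
#' @param behavior Behavioral tibble ([simulate_behavior()]) matching
#'   `design` (uses `saccade_endpoint_angle` and `rt_ms`).
#' @param noise_sd Positional jitter SD, degrees (default 0).
#' @param blink_rate Expected blinks per trial (default 0); each blink
#'   drops ~100 ms of samples at a uniform random time in the delay.
#' @param target_ecc Saccade amplitude, degrees (default 12).
#' @param t_range Trace window, seconds relative to delay onset.
#' @param fs Sampling rate, Hz (fixed at 500 by the recording convention).
#' @param seed Integer seed.
#' @return A list with `gaze` (tibble: `trial_id`, `time`, `x`, `y`,
#'   `valid`) and `truth` (tibble: `trial_id`, `onset`, `offset`,
#'   `amplitude`).
#' @export
simulate_gaze <- function(design, behavior, noise_sd = 0, blink_rate = 0,
                          target_ecc = 12, t_range = c(-1, 14), fs = 500,
                          seed = NULL) {
  stopifnot(nrow(design) == nrow(behavior), fs == 500)
  if (!is.null(seed)) set.seed(seed)
  dt <- 1 / fs
  tt <- seq(t_range[1], t_range[2], by = dt)

  traces <- vector("list", nrow(design))
  truths <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    onset <- design$t_response[i] + behavior$rt_ms[i] / 1000
    amp <- target_ecc
    dur <- 0.021 + 0.0022 * amp   # main-sequence duration
    ex <- amp * cos_deg(behavior$saccade_endpoint_angle[i])
    ey <- amp * sin_deg(behavior$saccade_endpoint_angle[i])
    tau <- pmin(pmax((tt - onset) / dur, 0), 1)
    # minimum-jerk displacement profile
    s <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
    x <- ex * s
    y <- ey * s
    valid <- rep(TRUE, length(tt))
    if (blink_rate > 0) {
      n_blinks <- stats::rpois(1, blink_rate)
      for (b in seq_len(n_blinks)) {
        t0 <- stats::runif(1, 0, design$t_response[i] - 0.2)
        valid[tt >= t0 & tt < t0 + 0.1] <- FALSE
      }
    }
    if (noise_sd > 0) {
      x <- x + stats::rnorm(length(tt), 0, noise_sd)
      y <- y + stats::rnorm(length(tt), 0, noise_sd)
    }
    x[!valid] <- NA_real_
    y[!valid] <- NA_real_
    traces[[i]] <- tibble::tibble(
      trial_id = design$trial_id[i], time = tt, x = x, y = y, valid = valid
    )
    truths[[i]] <- tibble::tibble(
      trial_id = design$trial_id[i], onset = onset, offset = onset + dur,
      amplitude = amp
    )
  }
  list(gaze = dplyr::bind_rows(traces), truth = dplyr::bind_rows(truths))
}
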