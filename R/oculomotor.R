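#' Preprocess a gaze trace
#'
#' Ordered stages, mirroring standard memory-guided saccade pipelines:
#' (1) pixel-to-degree conversion when a screen `geometry` is supplied;
#' (2) invalidation of blink/extreme samples (`NA` or beyond
#' `extreme_deg`); (3) Gaussian smoothing with a 5 ms SD kernel;
#' (4) per-trial drift correction, subtracting the mean eye position over
#' known fixation epochs; (5) optional run-wise recalibration fitting a
#' 3rd-order polynomial mapping measured to true positions on each axis
#' independently.
#'
#' @param gaze Tibble with `time` (seconds, uniform 500 Hz), `x`, `y`
#'   (pixels or degrees), optional `valid` flag, and `trial_id` when drift
#'   correction is per trial.
#' @param geometry Optional list with `px_per_deg` and screen center
#'   `center_px = c(x, y)`; `NULL` means the trace is already in degrees.
#' @param fixation_window Window (seconds, trial-relative `time`) known to
#'   be fixation, used for drift correction; `NULL` skips the stage.
#' @param calibration Optional tibble with one row per trial: `trial_id`,
#'   measured `x`, `y` (raw endpoint estimates) and true `target_x`,
#'   `target_y`; triggers cubic recalibration. `NULL` skips it.
#' @param smooth_sd_ms Gaussian kernel SD, milliseconds (default 5).
#' @param extreme_deg Samples beyond this eccentricity are invalidated.
#' @return The gaze tibble in degrees with updated `x`, `y`, `valid`.
#' @export
preprocess_gaze <- function(gaze, geometry = NULL, fixation_window = NULL,
                            calibration = NULL, smooth_sd_ms = 5,
                            extreme_deg = 30) {
  stopifnot(all(c("time", "x", "y") %in% names(gaze)))
  dt <- stats::median(diff(gaze$time))
  if (!("valid" %in% names(gaze))) gaze$valid <- TRUE

  if (!is.null(geometry)) {
    gaze$x <- (gaze$x - geometry$center_px[1]) / geometry$px_per_deg
    gaze$y <- (gaze$y - geometry$center_px[2]) / geometry$px_per_deg
  }
  bad <- !gaze$valid | !is.finite(gaze$x) | !is.finite(gaze$y) |
    sqrt(gaze$x^2 + gaze$y^2) > extreme_deg
  gaze$valid <- !bad
  gaze$x[bad] <- NA_real_
  gaze$y[bad] <- NA_real_

  gaze$x <- gaussian_smooth(gaze$x, smooth_sd_ms / 1000, dt)
  gaze$y <- gaussian_smooth(gaze$y, smooth_sd_ms / 1000, dt)

  if (!is.null(fixation_window)) {
    grp <- if ("trial_id" %in% names(gaze)) gaze$trial_id else
      rep(1L, nrow(gaze))
    for (g in unique(grp)) {
      sel <- grp == g
      fix <- sel & gaze$valid & gaze$time >= fixation_window[1] &
        gaze$time < fixation_window[2]
      if (sum(fix, na.rm = TRUE) < 10) {
        stop(sprintf(
          "trial %s: insufficient valid fixation samples for drift correction",
          g))
      }
      gaze$x[sel] <- gaze$x[sel] - mean(gaze$x[fix], na.rm = TRUE)
      gaze$y[sel] <- gaze$y[sel] - mean(gaze$y[fix], na.rm = TRUE)
    }
  }

  if (!is.null(calibration)) {
    if (nrow(calibration) < 5) {
      stop("cubic recalibration needs at least 5 calibration trials")
    }
    fit_axis <- function(meas, true) {
      stats::lm(true ~ stats::poly(meas, 3, raw = TRUE))
    }
    fx <- fit_axis(calibration$x, calibration$target_x)
    fy <- fit_axis(calibration$y, calibration$target_y)
    ok <- gaze$valid
    gaze$x[ok] <- unname(stats::predict(fx, data.frame(meas = gaze$x[ok])))
    gaze$y[ok] <- unname(stats::predict(fy, data.frame(meas = gaze$y[ok])))
  }
  gaze
}

# Gaussian FIR smoothing; NA gaps are preserved as NA and excluded from
# the kernel normalisation near gap edges
gaussian_smooth <- function(x, sd_s, dt) {
  if (sd_s <= 0) return(x)
  half <- max(1L, ceiling(4 * sd_s / dt))
  k <- stats::dnorm(seq(-half, half) * dt, sd = sd_s)
  k <- k / sum(k)
  na <- is.na(x)
  x0 <- ifelse(na, 0, x)
  w0 <- as.numeric(!na)
  num <- stats::filter(c(rep(x0[1] * w0[1], half), x0,
                         rep(x0[length(x0)] * w0[length(w0)], half)),
                       k, sides = 2)
  den <- stats::filter(c(rep(w0[1], half), w0, rep(w0[length(w0)], half)),
                       k, sides = 2)
  out <- as.numeric(num / pmax(den, 1e-12))[half + seq_along(x)]
  out[na] <- NA_real_
  out
}

#' Detect saccades with a velocity threshold
#'
#' Marks as saccades the maximal runs of samples whose speed strictly
#' exceeds `velocity_deg_s` (30 deg/s by default) for at least
#' `min_dur_ms` (7.5 ms, i.e. 4 samples at 500 Hz, rounding up) and whose
#' net gaze displacement is at least `min_amp_deg` (0.25 deg). Speed comes
#' from central differences on the (smoothed) trace; invalid samples break
#' runs. The reported onset is the last sub-threshold sample before the
#' run (the true crossing lies between it and the first supra-threshold
#' sample); the offset is the first sub-threshold sample after it.
#'
#' @param gaze Preprocessed gaze tibble (`time`, `x`, `y`, `valid`).
#' @param velocity_deg_s Speed threshold, degrees/s (strict inequality).
#' @param min_dur_ms Minimum supra-threshold duration, ms.
#' @param min_amp_deg Minimum net displacement, degrees.
#' @return A tibble with one row per saccade: `onset`, `offset`,
#'   `duration`, `amplitude`, `peak_velocity`, `x_end`, `y_end`.
#' @export
detect_saccades <- function(gaze, velocity_deg_s = 30, min_dur_ms = 7.5,
                            min_amp_deg = 0.25) {
  stopifnot(all(c("time", "x", "y") %in% names(gaze)))
  if (!("valid" %in% names(gaze))) gaze$valid <- TRUE
  n <- nrow(gaze)
  dt <- stats::median(diff(gaze$time))
  vx <- c(NA, (gaze$x[-(1:2)] - gaze$x[-((n - 1):n)]) / (2 * dt), NA)
  vy <- c(NA, (gaze$y[-(1:2)] - gaze$y[-((n - 1):n)]) / (2 * dt), NA)
  speed <- sqrt(vx^2 + vy^2)
  over <- !is.na(speed) & gaze$valid & speed > velocity_deg_s

  min_samples <- ceiling(min_dur_ms / 1000 / dt)
  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values & r$lengths >= min_samples)

  rows <- lapply(keep, function(j) {
    i0 <- starts[j]
    i1 <- ends[j]
    on <- max(i0 - 1L, 1L)   # last sub-threshold sample before the run
    off <- min(i1 + 1L, n)   # first sub-threshold sample after it
    amp <- sqrt((gaze$x[off] - gaze$x[on])^2 + (gaze$y[off] - gaze$y[on])^2)
    if (is.na(amp) || amp < min_amp_deg) return(NULL)
    tibble::tibble(
      onset = gaze$time[on], offset = gaze$time[off],
      duration = gaze$time[off] - gaze$time[on],
      amplitude = amp,
      peak_velocity = max(speed[i0:i1]),
      x_end = gaze$x[off], y_end = gaze$y[off]
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(onset = numeric(), offset = numeric(),
                          duration = numeric(), amplitude = numeric(),
                          peak_velocity = numeric(), x_end = numeric(),
                          y_end = numeric())
  }
  out
}

#' Score a memory-guided saccade trial
#'
#' The behavioral report is the final eye position before the memory
#' target reappears (after any corrective saccades); RT is the onset of
#' the initial saccade in the response window relative to the response
#' cue. A trial is excluded when any of the following holds (flags are
#' conjunctive and order-independent): no saccade in the response window;
#' initial saccade duration of 150 ms or more; initial saccade amplitude
#' under 5 degrees; endpoint further than 5 degrees (Euclidean) from the
#' target; or a fixation excursion of 2.5 degrees or more during the
#' delay.
#'
#' @param gaze Preprocessed gaze tibble for one trial (`time` relative to
#'   delay onset).
#' @param events Saccade tibble from [detect_saccades()] on this trial.
#' @param trial One row of the trial tibble (needs `target_angle`,
#'   `t_response`, ids).
#' @param target_ecc Target eccentricity, degrees (default 12).
#' @param reappear_delay Seconds from response cue to target
#'   reappearance (default 0.8).
#' @param max_duration_s,min_amp_deg,max_err_deg,fix_break_deg Exclusion
#'   thresholds.
#' @return A one-row tibble: ids, `saccade_endpoint_angle`,
#'   `memory_error` (signed degrees), `rt_ms`, `excluded`,
#'   `exclude_reason`.
#' @export
score_trial <- function(gaze, events, trial, target_ecc = 12,
                        reappear_delay = 0.8, max_duration_s = 0.150,
                        min_amp_deg = 5, max_err_deg = 5,
                        fix_break_deg = 2.5) {
  t_resp <- trial$t_response
  t_reappear <- t_resp + reappear_delay
  reasons <- character()

  delay_sel <- gaze$valid & gaze$time >= 0 & gaze$time < t_resp
  if (any(sqrt(gaze$x[delay_sel]^2 + gaze$y[delay_sel]^2) >= fix_break_deg,
          na.rm = TRUE)) {
    reasons <- c(reasons, "fixation_break")
  }

  win <- events[events$onset >= t_resp & events$onset < t_reappear, ,
                drop = FALSE]
  endpoint <- c(NA_real_, NA_real_)
  rt_ms <- NA_real_
  err <- NA_real_
  end_angle <- NA_real_
  if (nrow(win) == 0) {
    reasons <- c(reasons, "no_saccade")
  } else {
    initial <- win[1, ]
    rt_ms <- (initial$onset - t_resp) * 1000
    if (initial$duration >= max_duration_s) {
      reasons <- c(reasons, "long_duration")
    }
    if (initial$amplitude < min_amp_deg) {
      reasons <- c(reasons, "small_amplitude")
    }
    pre <- which(gaze$valid & gaze$time < t_reappear)
    if (length(pre) > 0) {
      i_end <- max(pre)
      endpoint <- c(gaze$x[i_end], gaze$y[i_end])
      end_angle <- angle_mod360(atan2(endpoint[2], endpoint[1]) * 180 / pi)
      err <- wrap_angle(end_angle - trial$target_angle)
      tx <- target_ecc * cos_deg(trial$target_angle)
      ty <- target_ecc * sin_deg(trial$target_angle)
      if (sqrt((endpoint[1] - tx)^2 + (endpoint[2] - ty)^2) > max_err_deg) {
        reasons <- c(reasons, "endpoint_error")
      }
    }
  }

  tibble::tibble(
    participant_id = trial$participant_id %||% NA_character_,
    run_id = trial$run_id %||% NA_integer_,
    trial_id = trial$trial_id,
    condition = trial$condition %||% NA_character_,
    saccade_endpoint_angle = end_angle,
    memory_error = err,
    rt_ms = rt_ms,
    excluded = length(reasons) > 0,
    exclude_reason = if (length(reasons)) paste(reasons, collapse = ";")
      else NA_character_
  )
}

#' Behavioral precision and RT summaries per condition
#'
#' Per participant and condition: memory precision as the sample SD of the
#' target-aligned saccade endpoint polar-angle errors (wrapped signed
#' errors; appropriate in the small-error regime) and the mean RT over
#' valid trials.
#'
#' @param records Scored-trial tibble ([score_trial()] rows or
#'   [simulate_behavior()]).
#' @param min_trials Minimum valid trials per cell (default 2).
#' @return A tibble with `participant_id`, `condition`, `n`,
#'   `precision_sd`, `mean_rt_ms`.
#' @export
behavior_summary <- function(records, min_trials = 2) {
  ok <- records[!records$excluded & !is.na(records$memory_error), ]
  out <- ok |>
    dplyr::group_by(.data$participant_id, .data$condition) |>
    dplyr::summarise(
      n = dplyr::n(),
      precision_sd = stats::sd(.data$memory_error),
      mean_rt_ms = mean(.data$rt_ms),
      .groups = "drop"
    )
  if (any(out$n < min_trials)) {
    stop("fewer than the minimum valid trials in some participant x condition cells")
  }
  out
}
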