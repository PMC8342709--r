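test_that("saccade detection recovers noiseless ground truth within one sample", {
  fix <- clean_trial_gaze(endpoint_angle = 30, rt_ms = 250, seed = 2)
  ev <- detect_saccades(fix$gaze)
  expect_equal(nrow(ev), 1) # no spurious events on a clean trace
  dt <- 1 / 500
  expect_lte(abs(ev$onset - fix$truth$onset), dt + 1e-9)
  expect_equal(ev$amplitude, 12, tolerance = 0.05)
  expect_gt(ev$peak_velocity, 200)
})

test_that("amplitude and velocity thresholds are sharp", {
  tt <- seq(0, 1, by = 1 / 500)
  # 0.2 deg jitter: below the 0.25 deg amplitude threshold
  set.seed(3)
  g_small <- tibble::tibble(time = tt, x = 0.1 * sin(2 * pi * 3 * tt),
                            y = 0, valid = TRUE)
  expect_equal(nrow(detect_saccades(g_small)), 0)
  # velocity plateau exactly at 30 deg/s: strict inequality, no events
  # (dyadic time grid keeps the central-difference speed exactly 30)
  t2 <- (0:1000) / 512
  g_plateau <- tibble::tibble(time = t2, x = 30 * t2, y = 0, valid = TRUE)
  expect_equal(nrow(detect_saccades(g_plateau)), 0)
  # slightly above threshold is detected once amplitude suffices
  g_over <- tibble::tibble(time = t2, x = 31 * t2, y = 0, valid = TRUE)
  expect_gt(nrow(detect_saccades(g_over)), 0)
})

test_that("blink samples are invalidated and span the blink", {
  fix <- clean_trial_gaze(seed = 4)
  g <- fix$gaze
  g$x[g$time >= 5 & g$time < 5.1] <- NA # mid-delay blink
  pre <- preprocess_gaze(g, fixation_window = c(-0.5, 0))
  expect_true(all(!pre$valid[pre$time >= 5 & pre$time < 5.1]))
  expect_true(all(is.na(pre$x[!pre$valid])))
})

test_that("drift correction removes a constant fixation offset exactly", {
  fix <- clean_trial_gaze(seed = 5)
  g <- fix$gaze
  g$x <- g$x + 0.5
  pre <- preprocess_gaze(g, fixation_window = c(-0.5, 0))
  ref <- preprocess_gaze(fix$gaze, fixation_window = c(-0.5, 0))
  expect_equal(pre$x, ref$x, tolerance = 1e-9)
})

test_that("run-wise cubic recalibration recovers true positions to < 0.05 deg", {
  # measured space m; the true position is a known cubic map of m, so the
  # recalibration fit can undo the miscalibration exactly
  truth_of <- function(m) 0.02 * m^3 - 0.05 * m^2 + 1.1 * m + 0.3
  set.seed(6)
  m_end <- runif(12, -10, 10)
  calib <- tibble::tibble(
    trial_id = 1:12, x = m_end, y = m_end,
    target_x = truth_of(m_end), target_y = truth_of(m_end)
  )
  tt <- seq(0, 2, by = 1 / 500)
  m_trace <- seq(-10, 10, length.out = length(tt))
  g <- tibble::tibble(time = tt, x = m_trace, y = m_trace, valid = TRUE)
  pre <- preprocess_gaze(g, calibration = calib, smooth_sd_ms = 0)
  expect_lt(max(abs(pre$x - truth_of(m_trace))), 0.05)
  expect_lt(max(abs(pre$y - truth_of(m_trace))), 0.05)
})

test_that("trial scoring reproduces hand-labeled exclusion decisions", {
  dt <- 1 / 500
  mk <- function(endpoint_angle, rt_ms, target_angle = 0, target_ecc = 12,
                 tweak = identity) {
    fix <- clean_trial_gaze(endpoint_angle = endpoint_angle, rt_ms = rt_ms,
                            target_angle = target_angle, seed = 7)
    if (target_ecc != 12) {
      sim <- simulate_gaze(fix$design,
                           tibble::tibble(
                             saccade_endpoint_angle = endpoint_angle,
                             rt_ms = rt_ms),
                           target_ecc = target_ecc, seed = 7)
      fix$gaze <- sim$gaze
    }
    fix$gaze <- tweak(fix$gaze)
    score_trial(fix$gaze, detect_saccades(fix$gaze), fix$design)
  }

  # 1: clean trial at the target: kept, error ~ 0, RT as simulated
  s1 <- mk(0, 250)
  expect_false(s1$excluded)
  expect_lt(abs(s1$memory_error), 0.5)
  expect_equal(s1$rt_ms, 250, tolerance = 4)
  # 2: 3 deg initial saccade: amplitude < 5 (and far from the target)
  s2 <- mk(0, 250, target_ecc = 3)
  expect_true(s2$excluded)
  expect_match(s2$exclude_reason, "small_amplitude")
  expect_match(s2$exclude_reason, "endpoint_error")
  # 3: 2.6 deg excursion during the delay: fixation break
  s3 <- mk(0, 250, tweak = function(g) {
    g$x[g$time >= 6 & g$time < 6.2] <- 2.6
    g
  })
  expect_true(s3$excluded)
  expect_match(s3$exclude_reason, "fixation_break")
  # 4: saccade after target reappearance: no saccade in the window
  s4 <- mk(0, 900)
  expect_true(s4$excluded)
  expect_match(s4$exclude_reason, "no_saccade")
  # 5: slow 160 ms movement: duration >= 150 ms
  s5 <- mk(0, 250, tweak = function(g) {
    ramp <- g$time >= 12.25 & g$time < 12.41
    g$x[g$time >= 12.41] <- 12
    g$x[ramp] <- 12 * (g$time[ramp] - 12.25) / 0.16
    g$x[g$time < 12.25] <- 0
    g$y[] <- 0
    g
  })
  expect_true(s5$excluded)
  expect_match(s5$exclude_reason, "long_duration")
  # 6: endpoint 30 deg of polar angle off a 12 deg target: > 5 deg error
  s6 <- mk(30, 250, target_angle = 0)
  expect_true(s6$excluded)
  expect_match(s6$exclude_reason, "endpoint_error")
  # 7: endpoint 10 deg off: chord 2.09 deg, within tolerance -> kept
  s7 <- mk(10, 250, target_angle = 0)
  expect_false(s7$excluded)
  expect_equal(s7$memory_error, 10, tolerance = 0.5)
  # 8: clockwise endpoint gives a negative signed error
  s8 <- mk(350, 250, target_angle = 0)
  expect_false(s8$excluded)
  expect_equal(s8$memory_error, -10, tolerance = 0.5)
  # 9: fixation excursion of 2.0 deg stays below the break threshold
  s9 <- mk(0, 250, tweak = function(g) {
    g$x[g$time >= 6 & g$time < 6.2] <- 2.0
    g
  })
  expect_false(s9$excluded)
  # 10: blink during the delay does not by itself exclude the trial
  s10 <- mk(0, 250, tweak = function(g) {
    sel <- g$time >= 5 & g$time < 5.1
    g$x[sel] <- NA
    g$valid[sel] <- FALSE
    g
  })
  expect_false(s10$excluded)
})

test_that("behavioral summaries use the sample SD of aligned errors", {
  rec <- tibble::tibble(
    participant_id = "p01",
    condition = rep(c("distractor_absent", "distractor_present"), each = 3),
    memory_error = c(-2, 0, 2, -4, 0, 4),
    rt_ms = c(300, 310, 320, 340, 350, 360),
    excluded = FALSE
  )
  out <- behavior_summary(rec)
  expect_equal(out$precision_sd[out$condition == "distractor_absent"], 2)
  expect_equal(out$precision_sd[out$condition == "distractor_present"], 4)
  expect_equal(out$mean_rt_ms, c(310, 350))
  expect_error(behavior_summary(rec[c(1, 4:6), ]), "minimum valid trials")
})

test_that("estimated precision rises monotonically with motor noise", {
  design <- generate_design(30, seed = 8)
  sds <- c(1, 3, 6)
  est <- vapply(seq_along(sds), function(i) {
    b <- simulate_behavior(design, motor_sd = sds[i], present_sd_scale = 1,
                           attract_bias = 0, seed = 9 + i)
    stats::sd(b$memory_error)
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})
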