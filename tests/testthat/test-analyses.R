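test_that("epoch averaging follows the half-open TR-inclusion convention", {
  design <- generate_design(1, seed = 1)
  pop <- generate_population(10, seed = 2)
  ts <- simulate_timeseries(design, pop, noise_sd = 0.5, seed = 3)
  expect_equal(attr(epoch_average(ts, "TRAIN"), "n_tr"), 9L)
  expect_equal(attr(epoch_average(ts, "PRE"), "n_tr"), 2L) # onsets 3.75, 4.5
  expect_equal(attr(epoch_average(ts, "DIST"), "n_tr"), 2L)
  expect_equal(attr(epoch_average(ts, "POST"), "n_tr"), 2L)
  # a constant series averages to the constant
  ts$data[] <- 4.2
  expect_true(all(epoch_average(ts, "TRAIN") == 4.2))
  expect_error(epoch_average(ts, c(100, 101)), "no TR onsets")
  expect_error(epoch_average(ts, "NOPE"), "unknown epoch")
})

test_that("behavioral bias equals the hand-computed flipped mean on a toy table", {
  trials <- tibble::tibble(
    participant_id = "p01", trial_id = 1:5,
    condition = "distractor_present",
    relative_distractor_angle = c(10, -8, 11, -12, 5)
  )
  records <- tibble::tibble(
    participant_id = "p01", trial_id = 1:5,
    memory_error = c(3, -2, -1, 4, 0)
  )
  # flipped toward-distractor errors: 3, 2, -1, -4, 0 -> mean 0
  res <- behavioral_bias(records, trials, n_perm = 100, seed = 1)
  expect_equal(res$bias, mean(c(3, 2, -1, -4, 0)))

  # all errors exactly toward the distractor by 2 deg
  rec2 <- records
  rec2$memory_error <- 2 * sign(trials$relative_distractor_angle)
  expect_equal(behavioral_bias(rec2, trials, n_perm = 100, seed = 1)$bias, 2)
})

test_that("counterbalanced distractors wash out of target-aligned averages", {
  # identical noiseless simulations except for the distractor response:
  # averaging over the seven counterbalanced bins must cancel its
  # contribution to target-aligned fidelity
  design <- generate_design(8, seed = 41)
  pop <- generate_population(120, seed = 42)
  train <- generate_training_design(2, seed = 43)
  ts_tr <- simulate_timeseries(train, pop, noise_sd = 0, zscore = FALSE)
  model <- train_encoding_model(ts_tr, train$target_angle)
  # suppression off: isolate the additive distractor response
  ts_on <- simulate_timeseries(design, pop, noise_sd = 0,
                               distractor_gain = 1.5,
                               target_suppression = 0, zscore = FALSE)
  ts_off <- simulate_timeseries(design, pop, noise_sd = 0,
                                distractor_gain = 0, zscore = FALSE)
  pres <- design$condition == "distractor_present"
  f_on <- epoch_metrics(ts_on, design, model, "DIST", "target")$fidelity[pres]
  f_off <- epoch_metrics(ts_off, design, model, "DIST",
                         "target")$fidelity[pres]
  f_dist <- mean(epoch_metrics(ts_on, design, model, "DIST",
                               "distractor")$fidelity)
  # the distractor representation itself is strong ...
  expect_gt(f_dist, 5 * abs(mean(f_on - f_off)))
  # ... yet the bin-averaged target-aligned fidelity is unchanged
  expect_lt(abs(mean(f_on - f_off)), 0.1 * mean(f_off))
})

test_that("RF-sorted time courses separate tuned from opposite voxels", {
  design <- generate_design(2, seed = 51)
  pop <- generate_population(300, seed = 52, r2_range = c(0.2, 0.8))
  ts <- simulate_timeseries(design, pop, noise_sd = 0, zscore = FALSE,
                            seed = 53)
  tc <- rf_sorted_timecourse(ts, pop, design, "target")
  delay <- tc$time >= 3.75 & tc$time < 12
  for (cond in unique(tc$condition)) {
    m_in <- mean(tc$activation[tc$rf == "in" & delay & tc$condition == cond])
    m_out <- mean(tc$activation[tc$rf == "out" & delay & tc$condition == cond])
    expect_gt(m_in, m_out)
  }
  # baseline window mean is zero after correction, per time course
  base <- tc$time >= -2.25 & tc$time < 0
  agg <- tapply(tc$activation[base], paste(tc$condition, tc$rf)[base], mean)
  expect_true(all(abs(agg) < 1e-10))
})

test_that("RF selection boundaries are inclusive and failures are named", {
  design <- generate_design(1, seed = 54)[1, ]
  design$target_angle <- 0
  pop <- tibble::tibble(
    voxel = 1:2, prf_angle = c(15, 165), prf_ecc = 5, prf_size = 2,
    r2 = 0.5, tuning_width = 30, gain_delay = 1, gain_distractor = 1
  )
  ts <- simulate_timeseries(design, pop, noise_sd = 0, zscore = FALSE)
  tc <- rf_sorted_timecourse(ts, pop, design, "target")
  expect_setequal(unique(tc$rf), c("in", "out")) # both boundary voxels count
  # remove the RF-out voxel: the failure names the trial
  pop2 <- pop[1, ]
  ts2 <- simulate_timeseries(design, pop2, noise_sd = 0, zscore = FALSE)
  expect_error(rf_sorted_timecourse(ts2, pop2, design, "target"),
               "no qualifying RF-out")
})
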