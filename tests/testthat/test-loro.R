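test_that("matched train/test indices reduce to leave-one-run-out decoding", {
  w <- small_world(seed = 61, n_runs = 4, noise_sd = 0.5)
  gen <- loro_generalization(w$ts_test, w$design, w$model$basis, "epoch")
  expect_s3_class(gen, "wm_generalization")
  expect_equal(nrow(gen), 9)
  n_pres <- sum(w$design$condition == "distractor_present")
  expect_true(all(gen$n_trials == n_pres)) # every present trial tested once

  # oracle for one diagonal cell: explicit leave-one-run-out by hand
  pres <- which(w$design$condition == "distractor_present")
  b_all <- epoch_average(w$ts_test, "PRE")[pres, , drop = FALSE]
  angles <- w$design$target_angle[pres]
  runs <- w$ts_test$run_ids[pres]
  fids <- c()
  for (held in unique(runs)) {
    trn <- runs != held
    m <- estimate_weights(channel_matrix(angles[trn], w$model$basis),
                          b_all[trn, , drop = FALSE], w$model$basis)
    ch <- invert_channels(b_all[!trn, , drop = FALSE], m)
    fids <- c(fids, wmiem:::fidelity_rows(ch, w$model$basis, angles[!trn]))
  }
  expect_equal(gen$fidelity[gen$train == "PRE" & gen$test == "PRE"],
               mean(fids), tolerance = 1e-10)
})

test_that("stable codes generalize across epochs; morphed codes do not", {
  # stable code: the same tuning generates all epochs
  w <- small_world(seed = 62, n_runs = 6, noise_sd = 0.5,
                   distractor_gain = 0)
  gen <- loro_generalization(w$ts_test, w$design, w$model$basis, "epoch")
  expect_true(all(gen$fidelity > 0))
  # no block structure: every cross-epoch cell is comparable to the
  # diagonal cell of the same *test* epoch (cell scale tracks the test
  # epoch's signal amplitude under a fixed per-cell training procedure)
  dg <- function(g, e) g$fidelity[g$train == e & g$test == e]
  for (i in which(gen$train != gen$test)) {
    expect_gt(gen$fidelity[i], 0.3 * dg(gen, gen$test[i]))
  }

  # morphed code: remap every voxel's preferred angle after the distractor
  design <- w$design
  pop <- w$pop
  pop2 <- pop
  set.seed(63)
  pop2$prf_angle <- (pop$prf_angle + runif(nrow(pop), 0, 360)) %% 360
  ts_pre <- simulate_timeseries(design, pop, noise_sd = 0.5,
                                distractor_gain = 0, seed = 64)
  ts_post <- simulate_timeseries(design, pop2, noise_sd = 0.5,
                                 distractor_gain = 0, seed = 65)
  morph <- ts_pre
  post_tr <- which(ts_pre$tr_onsets >= 9.75)
  morph$data[, post_tr, ] <- ts_post$data[, post_tr, ]
  gen_m <- loro_generalization(morph, design, w$model$basis, "epoch")
  diag_pre <- gen_m$fidelity[gen_m$train == "PRE" & gen_m$test == "PRE"]
  diag_post <- gen_m$fidelity[gen_m$train == "POST" & gen_m$test == "POST"]
  cross1 <- gen_m$fidelity[gen_m$train == "PRE" & gen_m$test == "POST"]
  cross2 <- gen_m$fidelity[gen_m$train == "POST" & gen_m$test == "PRE"]
  # diagonal blocks stay positive while the cross-epoch cells collapse
  expect_gt(diag_pre, 0)
  expect_gt(diag_post, 0)
  expect_lt(abs(cross1), 0.35 * diag_post)
  expect_lt(abs(cross2), 0.35 * diag_pre)
})

test_that("generalization rejects impossible partitions", {
  w <- small_world(seed = 66, n_runs = 1, noise_sd = 0.5)
  expect_error(loro_generalization(w$ts_test, w$design, w$model$basis),
               "at least 2 runs")
  absent_only <- w$design[w$design$condition == "distractor_absent", ]
  ts_sub <- w$ts_test
  keep <- which(w$design$condition == "distractor_absent")
  ts_sub$data <- ts_sub$data[keep, , , drop = FALSE]
  ts_sub$run_ids <- ts_sub$run_ids[keep]
  ts_sub$trial_ids <- ts_sub$trial_ids[keep]
  expect_error(loro_generalization(ts_sub, absent_only, w$model$basis),
               "no distractor-present trials")
})
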