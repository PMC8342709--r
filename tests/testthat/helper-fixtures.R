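# shared small fixtures, all built in code under fixed seeds

small_world <- function(seed = 11, n_runs = 4, n_voxels = 120,
                        noise_sd = 0, distractor_gain = 1, zscore = TRUE,
                        neural_bias = 0) {
  design <- generate_design(n_runs, seed = seed)
  pop <- generate_population(n_voxels, seed = seed + 1)
  train <- generate_training_design(2, seed = seed + 2)
  ts_train <- simulate_timeseries(train, pop, noise_sd = noise_sd,
                                  seed = seed + 3, zscore = zscore)
  ts_test <- simulate_timeseries(design, pop, noise_sd = noise_sd,
                                 neural_bias = neural_bias,
                                 distractor_gain = distractor_gain,
                                 seed = seed + 4, zscore = zscore)
  model <- train_encoding_model(ts_train, train$target_angle)
  list(design = design, pop = pop, train = train, ts_train = ts_train,
       ts_test = ts_test, model = model)
}

# one clean simulated saccade trial at 500 Hz for oculomotor tests
clean_trial_gaze <- function(endpoint_angle = 30, rt_ms = 250,
                             target_angle = endpoint_angle, seed = 1) {
  design <- generate_design(1, seed = seed)[1, ]
  design$target_angle <- target_angle
  behavior <- tibble::tibble(saccade_endpoint_angle = endpoint_angle,
                             rt_ms = rt_ms)
  sim <- simulate_gaze(design, behavior, seed = seed)
  list(design = design, gaze = sim$gaze, truth = sim$truth)
}
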