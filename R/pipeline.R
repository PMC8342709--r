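#' Build a pipeline configuration
#'
#' Declarative configuration for the end-to-end demonstration pipeline.
#' Defaults mirror the study conditions the simulator emulates: 7
#' participants, runs of ten trials (7 distractor-present / 3 absent),
#' training runs of 16 staggered positions, a 750 ms TR grid, and 1000
#' permutations. The configuration is fully serializable
#' ([write_config()]/[read_config()]) and a persisted configuration
#' re-runs to identical outputs under its recorded seed.
#'
#' @param seed Master seed; all stage seeds are derived from it.
#' @param n_participants,n_runs,n_train_runs,n_voxels Simulation sizes.
#' @param noise_sd BOLD noise SD, a.u.
#' @param neural_bias_sd SD of the trial-wise neural bias, degrees.
#' @param neural_attract Mean neural attraction toward the distractor on
#'   present trials, degrees.
#' @param coupling Neural-to-behavioral coupling weight.
#' @param attract_bias Behavioral attraction toward the distractor, degrees.
#' @param motor_sd Motor noise SD, degrees.
#' @param distractor_gain Distractor response gain.
#' @param n_perm Number of permutations for inference stages.
#' @param n_channels,size_constant,exponent Channel-basis parameters.
#' @param out_dir Output directory or `NULL` to skip writing.
#' @return A list of class `wm_config`.
#' @export
pipeline_config <- function(seed = 1, n_participants = 7, n_runs = 12,
                            n_train_runs = 4, n_voxels = 160,
                            noise_sd = 1.5, neural_bias_sd = 10,
                            neural_attract = 5, coupling = 0.3,
                            attract_bias = 1, motor_sd = 2,
                            distractor_gain = 1, n_perm = 1000,
                            n_channels = 8, size_constant = 180,
                            exponent = 8, out_dir = NULL) {
  cfg <- as.list(environment())
  structure(cfg, class = "wm_config")
}

#' @export
print.wm_config <- function(x, ...) {
  cat("<wm_config>\n")
  for (n in names(x)) {
    cat(sprintf("  %s: %s\n", n,
                if (is.null(x[[n]])) "NULL" else paste(x[[n]], collapse = " ")))
  }
  invisible(x)
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `write_config()` returns `path` invisibly; `read_config()`
#'   returns the `wm_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg[names(cfg) %in% names(formals(pipeline_config))])
}

# deterministic stage seeds derived from the master seed (kept < 2^31)
stage_seed <- function(seed, stage, k = 0) {
  (seed * 7919 + match(stage, c("design", "train", "bold", "behavior",
                                "gaze", "stats")) * 104729 + k) %% 2147483647
}

#' Run the end-to-end demonstration pipeline on synthetic data
#'
#' Executes the full analysis flow per participant: simulate the
#' independent training task and the distractor experiment, estimate a
#' frozen encoding model on the training delay-period average, compute
#' target- and distractor-aligned fidelity time courses, per-epoch trial
#' metrics, the run-wise paired permutation t-test (present vs absent
#' fidelity per epoch), the leave-one-run-out epoch generalization, the
#' behavioral-bias and neural-behavioral coupling analyses on
#' near-distractor trials, and behavioral summaries. Writes tables and a
#' JSON sidecar to `config$out_dir` when set.
#'
#' @param config A [pipeline_config()].
#' @return A named list (`wm_results`) with elements `trials`, `behavior`,
#'   `fidelity_target`, `fidelity_distractor`, `epoch_fidelity`,
#'   `epoch_tests`, `generalization`, `bias`, `coupling`,
#'   `behavior_summary`, and `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "wm_config"))
  basis <- channel_basis(config$n_channels, config$size_constant,
                         config$exponent)
  design <- generate_design(config$n_runs, config$n_participants,
                            seed = stage_seed(config$seed, "design"))
  train_design <- generate_training_design(
    config$n_train_runs, config$n_participants,
    seed = stage_seed(config$seed, "train"))

  participants <- unique(design$participant_id)
  per_part <- purrr::map(seq_along(participants), function(pi) {
    pid <- participants[pi]
    trials <- design[design$participant_id == pid, ]
    tr_trials <- train_design[train_design$participant_id == pid, ]
    pop <- generate_population(config$n_voxels,
                               seed = stage_seed(config$seed, "bold", pi))

    set.seed(stage_seed(config$seed, "bold", 1000 + pi))
    present <- trials$condition == "distractor_present"
    bias <- stats::rnorm(nrow(trials), 0, config$neural_bias_sd) +
      ifelse(present,
             config$neural_attract *
               sign(wrap_angle(trials$relative_distractor_angle)), 0)

    ts_train <- simulate_timeseries(
      tr_trials, pop, noise_sd = config$noise_sd,
      seed = stage_seed(config$seed, "bold", 2000 + pi))
    ts_test <- simulate_timeseries(
      trials, pop, noise_sd = config$noise_sd, neural_bias = bias,
      distractor_gain = config$distractor_gain,
      seed = stage_seed(config$seed, "bold", 3000 + pi))
    behavior <- simulate_behavior(
      trials, neural_bias = bias, coupling = config$coupling,
      attract_bias = config$attract_bias, motor_sd = config$motor_sd,
      seed = stage_seed(config$seed, "behavior", pi))

    model <- train_encoding_model(ts_train, tr_trials$target_angle, basis)
    fid_t <- dplyr::mutate(
      fidelity_timecourse(ts_test, trials, model, "target"),
      participant_id = pid, .before = 1)
    fid_d <- dplyr::mutate(
      fidelity_timecourse(ts_test, trials, model, "distractor"),
      participant_id = pid, .before = 1)
    epochs <- dplyr::bind_rows(lapply(c("PRE", "DIST", "POST"), function(e) {
      dplyr::mutate(epoch_metrics(ts_test, trials, model, e, "target"),
                    participant_id = pid, .before = 1)
    }))
    gen <- dplyr::mutate(loro_generalization(ts_test, trials, basis, "epoch"),
                         participant_id = pid, .before = 1)
    list(trials = trials, behavior = behavior, fid_t = fid_t, fid_d = fid_d,
         epochs = epochs, gen = gen)
  })

  trials <- dplyr::bind_rows(purrr::map(per_part, "trials"))
  behavior <- dplyr::bind_rows(purrr::map(per_part, "behavior"))
  epoch_fid <- dplyr::bind_rows(purrr::map(per_part, "epochs"))

  # run-wise paired permutation t-test, present vs absent, per epoch
  run_means <- epoch_fid |>
    dplyr::group_by(.data$participant_id, .data$run_id, .data$epoch,
                    .data$condition) |>
    dplyr::summarise(fidelity = mean(.data$fidelity), .groups = "drop")
  epoch_tests <- dplyr::bind_rows(lapply(c("PRE", "DIST", "POST"),
                                         function(e) {
    tt <- perm_paired_ttest(
      run_means[run_means$epoch == e, ], "fidelity", "condition", "run_id",
      n_perm = config$n_perm,
      seed = stage_seed(config$seed, "stats", match(e, c("PRE", "DIST",
                                                         "POST"))))
    tibble::tibble(epoch = e, statistic = tt$statistic, p = tt$p)
  }))
  epoch_tests$p_adj <- fdr_correct(epoch_tests$p)$p_adj

  near <- near_distractor_select(trials)
  bias_res <- behavioral_bias(behavior, near, n_perm = config$n_perm,
                              seed = stage_seed(config$seed, "stats", 10))
  post <- epoch_fid[epoch_fid$epoch == "POST", ]
  coup_df <- dplyr::inner_join(
    dplyr::select(post, "participant_id", "trial_id", "decoding_error"),
    dplyr::select(behavior, "participant_id", "trial_id", "memory_error"),
    by = c("participant_id", "trial_id")) |>
    dplyr::inner_join(
      dplyr::select(near, "participant_id", "trial_id",
                    "relative_distractor_angle"),
      by = c("participant_id", "trial_id"))
  coup <- coupling_analysis(coup_df, n_perm = config$n_perm,
                            seed = stage_seed(config$seed, "stats", 11))

  results <- list(
    trials = trials,
    behavior = behavior,
    fidelity_target = dplyr::bind_rows(purrr::map(per_part, "fid_t")),
    fidelity_distractor = dplyr::bind_rows(purrr::map(per_part, "fid_d")),
    epoch_fidelity = epoch_fid,
    epoch_tests = epoch_tests,
    generalization = dplyr::bind_rows(purrr::map(per_part, "gen")),
    bias = bias_res,
    coupling = coup,
    behavior_summary = behavior_summary(behavior),
    config = config
  )
  class(results) <- "wm_results"

  if (!is.null(config$out_dir)) {
    tables <- results[c("trials", "behavior", "fidelity_target",
                        "fidelity_distractor", "epoch_fidelity",
                        "epoch_tests", "generalization",
                        "behavior_summary")]
    tables$coupling_by_participant <- coup$by_participant
    tables$coupling_quartiles <- coup$quartile
    write_store(tables, config$out_dir, config = unclass(config))
    write_config(config, file.path(config$out_dir, "config.yaml"))
  }
  results
}

#' @export
print.wm_results <- function(x, ...) {
  cat(sprintf(
    "<wm_results> %d participants, %d trials; DIST-epoch present-vs-absent p = %.4g; coupling p = %.4g\n",
    length(unique(x$trials$participant_id)), nrow(x$trials),
    x$epoch_tests$p[x$epoch_tests$epoch == "DIST"], x$coupling$p
  ))
  invisible(x)
}
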