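#' Per-TR fidelity time course of reconstructed representations
#'
#' For every TR: inverts the frozen encoding model on the trial x voxel
#' activation pattern, reconstructs over polar angle, aligns each trial to
#' its reference angle (the memory target, or the distractor — in which
#' case distractor-absent trials are dropped), and computes fidelity.
#'
#' @param ts An [roi_timeseries()].
#' @param trials Trial tibble matching `ts` rows.
#' @param model A frozen `encoding_model`.
#' @param align_to `"target"` or `"distractor"`.
#' @param by_trial If `TRUE`, return one row per trial x TR; otherwise a
#'   per-TR summary (mean, SEM over trials).
#' @return A tibble: either `trial_id`, `run_id`, `condition`, `time`,
#'   `fidelity` (`by_trial = TRUE`) or `time`, `fidelity`, `sem`,
#'   `n_trials`.
#' @export
fidelity_timecourse <- function(ts, trials, model,
                                align_to = c("target", "distractor"),
                                by_trial = FALSE) {
  align_to <- match.arg(align_to)
  stopifnot(nrow(trials) == dim(ts$data)[1])
  keep <- seq_len(nrow(trials))
  if (align_to == "distractor") {
    keep <- which(trials$condition == "distractor_present")
    if (length(keep) == 0) stop("no distractor-present trials to align")
  }
  ref <- switch(align_to,
    target = trials$target_angle[keep],
    distractor = trials$distractor_angle[keep]
  )
  n_tr <- length(ts$tr_onsets)
  per_tr <- purrr::map(seq_len(n_tr), function(t) {
    b <- ts$data[keep, t, , drop = FALSE]
    dim(b) <- c(length(keep), dim(ts$data)[3])
    ch <- invert_channels(b, model)
    tibble::tibble(
      trial_id = ts$trial_ids[keep],
      run_id = ts$run_ids[keep],
      condition = trials$condition[keep],
      time = ts$tr_onsets[t],
      fidelity = fidelity_rows(ch, model$basis, ref)
    )
  })
  out <- dplyr::bind_rows(per_tr)
  if (by_trial) return(out)
  dplyr::summarise(
    dplyr::group_by(out, .data$time),
    sem = stats::sd(.data$fidelity) / sqrt(dplyr::n()),
    n_trials = dplyr::n(),
    fidelity = mean(.data$fidelity),
    .groups = "drop"
  )[, c("time", "fidelity", "sem", "n_trials")]
}

#' Per-trial reconstruction metrics for one epoch
#'
#' Averages the time series over an epoch, inverts the model, and returns
#' per-trial fidelity, decoded angle, and signed decoding error relative to
#' the alignment reference.
#'
#' @inheritParams fidelity_timecourse
#' @param epoch Epoch name or `c(start, end)` window.
#' @return A tibble with `trial_id`, `run_id`, `condition`, `epoch`,
#'   `fidelity`, `decoded_angle`, `decoding_error`.
#' @export
epoch_metrics <- function(ts, trials, model, epoch = "POST",
                          align_to = c("target", "distractor")) {
  align_to <- match.arg(align_to)
  stopifnot(nrow(trials) == dim(ts$data)[1])
  keep <- seq_len(nrow(trials))
  if (align_to == "distractor") {
    keep <- which(trials$condition == "distractor_present")
    if (length(keep) == 0) stop("no distractor-present trials to align")
  }
  ref <- switch(align_to,
    target = trials$target_angle[keep],
    distractor = trials$distractor_angle[keep]
  )
  b <- epoch_average(ts, epoch)[keep, , drop = FALSE]
  ch <- invert_channels(b, model)
  decoded <- decode_rows(ch, model$basis)
  tibble::tibble(
    trial_id = ts$trial_ids[keep],
    run_id = ts$run_ids[keep],
    condition = trials$condition[keep],
    epoch = if (is.character(epoch)) epoch else
      sprintf("[%g,%g)", epoch[1], epoch[2]),
    fidelity = fidelity_rows(ch, model$basis, ref),
    decoded_angle = decoded,
    decoding_error = decoding_error(decoded, ref)
  )
}

#' Attraction of memory errors toward a nearby distractor
#'
#' On near-distractor trials, flips each signed memory error by the sign of
#' the relative distractor angle so that positive errors point toward the
#' distractor, averages within participants, and tests the group mean
#' against a sign-flip permutation null (errors are sign-flipped at the
#' trial level within each participant; two-tailed by default).
#'
#' @param records Behavioral tibble ([simulate_behavior()] or
#'   [score_trial()] output) with `participant_id`, `trial_id`,
#'   `memory_error`.
#' @param trials Trial tibble (used for the relative distractor angle);
#'   typically already restricted by [near_distractor_select()].
#' @param n_perm Number of permutations (default 1000).
#' @param tails `"two"` (default) or `"one"`.
#' @param seed Integer seed.
#' @return A list of class `wm_bias`: `bias` (group mean, degrees,
#'   positive = toward distractor), `by_participant`, `statistic` (t),
#'   `p`, `n_perm`, `tails`.
#' @export
behavioral_bias <- function(records, trials, n_perm = 1000,
                            tails = c("two", "one"), seed = NULL) {
  tails <- match.arg(tails)
  df <- dplyr::inner_join(
    dplyr::select(records, "participant_id", "trial_id", "memory_error",
                  dplyr::any_of("excluded")),
    dplyr::select(trials, "participant_id", "trial_id",
                  "relative_distractor_angle"),
    by = c("participant_id", "trial_id")
  )
  if ("excluded" %in% names(df)) df <- df[!df$excluded, ]
  df <- df[!is.na(df$relative_distractor_angle), ]
  if (nrow(df) == 0) stop("no valid near-distractor trials")
  if (!is.null(seed)) set.seed(seed)

  df$toward <- ifelse(df$relative_distractor_angle < 0,
                      -df$memory_error, df$memory_error)
  split_tw <- split(df$toward, df$participant_id)
  part_means <- vapply(split_tw, mean, numeric(1))
  obs_t <- one_sample_t(part_means)

  null_t <- vapply(seq_len(n_perm), function(i) {
    means <- vapply(split_tw, function(v) {
      mean(v * sample(c(-1, 1), length(v), replace = TRUE))
    }, numeric(1))
    one_sample_t(means)
  }, numeric(1))
  p <- perm_pvalue(obs_t, null_t, tails)

  structure(
    list(bias = mean(part_means),
         by_participant = tibble::tibble(
           participant_id = names(part_means), bias = unname(part_means)),
         statistic = obs_t, p = p, n_perm = n_perm, tails = tails),
    class = "wm_bias"
  )
}

#' @export
print.wm_bias <- function(x, ...) {
  cat(sprintf(
    "<wm_bias> mean bias toward distractor %.3f deg, t = %.2f, p = %.4g (%s-tailed, %d perms)\n",
    x$bias, x$statistic, x$p, x$tails, x$n_perm
  ))
  invisible(x)
}

one_sample_t <- function(x) {
  n <- length(x)
  if (n < 2) return(NA_real_)
  s <- stats::sd(x)
  if (s == 0) return(if (mean(x) == 0) 0 else sign(mean(x)) * Inf)
  mean(x) / (s / sqrt(n))
}

#' Univariate time courses for voxels tuned toward vs away from a stimulus
#'
#' For each trial, selects voxels by three receptive-field criteria
#' relative to the aligned stimulus (target or distractor): variance
#' explained at least `r2_min`, pRF eccentricity within `ecc_range`, and
#' wrapped polar-angle separation at most `rf_in_deg` (RF-in) or at least
#' `rf_out_deg` (RF-out; both boundaries inclusive). Voxel-mean time
#' courses are averaged over trials within condition and RF class, then
#' baseline-corrected by subtracting each time course's mean over
#' \[-2.25, 0) s.
#'
#' @param ts An [roi_timeseries()].
#' @param pop Voxel population tibble.
#' @param trials Trial tibble matching `ts`.
#' @param align_to `"target"` or `"distractor"`.
#' @param rf_in_deg,rf_out_deg Angular separation bounds, degrees.
#' @param ecc_range Eccentricity bounds, degrees.
#' @param r2_min Variance-explained threshold, fraction.
#' @param baseline Baseline window, seconds.
#' @return A tibble with `condition`, `rf` (`"in"`/`"out"`), `time`,
#'   `activation`, `n_trials`.
#' @export
rf_sorted_timecourse <- function(ts, pop, trials,
                                 align_to = c("target", "distractor"),
                                 rf_in_deg = 15, rf_out_deg = 165,
                                 ecc_range = c(2, 15), r2_min = 0.10,
                                 baseline = c(-2.25, 0)) {
  align_to <- match.arg(align_to)
  stopifnot(nrow(trials) == dim(ts$data)[1], nrow(pop) == dim(ts$data)[3])
  keep <- seq_len(nrow(trials))
  if (align_to == "distractor") {
    keep <- which(trials$condition == "distractor_present")
    if (length(keep) == 0) stop("no distractor-present trials to align")
  }
  stim <- switch(align_to,
    target = trials$target_angle,
    distractor = trials$distractor_angle
  )
  qualify <- pop$r2 >= r2_min & pop$prf_ecc >= ecc_range[1] &
    pop$prf_ecc <= ecc_range[2]

  rows <- purrr::map(keep, function(i) {
    sep <- circ_dist(pop$prf_angle, stim[i])
    vox_in <- which(qualify & sep <= rf_in_deg)
    vox_out <- which(qualify & sep >= rf_out_deg)
    if (length(vox_in) == 0 || length(vox_out) == 0) {
      stop(sprintf(
        "trial %d (participant %s): no qualifying RF-%s voxels",
        trials$trial_id[i], trials$participant_id[i],
        if (length(vox_in) == 0) "in" else "out"
      ))
    }
    n_t <- length(ts$tr_onsets)
    tc_in <- rowMeans(matrix(ts$data[i, , vox_in], nrow = n_t))
    tc_out <- rowMeans(matrix(ts$data[i, , vox_out], nrow = n_t))
    tibble::tibble(
      condition = trials$condition[i],
      rf = rep(c("in", "out"), each = length(ts$tr_onsets)),
      time = rep(ts$tr_onsets, 2),
      activation = c(tc_in, tc_out)
    )
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::group_by(.data$condition, .data$rf, .data$time) |>
    dplyr::summarise(activation = mean(.data$activation),
                     n_trials = dplyr::n(), .groups = "drop")
  # per-time-course baseline correction
  out |>
    dplyr::group_by(.data$condition, .data$rf) |>
    dplyr::mutate(activation = .data$activation -
                    mean(.data$activation[.data$time >= baseline[1] &
                                            .data$time < baseline[2]])) |>
    dplyr::ungroup()
}
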