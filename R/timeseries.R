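#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities (peak near 5 s, undershoot near 15 s),
#' normalized to unit peak. Used to smooth simulated neural boxcars into
#' BOLD-like time courses.
#'
#' @param t Time, seconds (non-negative part of the kernel support).
#' @param peak1,peak2 Shape parameters of the response and undershoot gamma
#'   components (rate 1), so the response peaks near `peak1 - 1` seconds.
#' @param undershoot_ratio Amplitude of the undershoot relative to the peak.
#' @return Numeric vector, kernel values at `t`, max 1.
#' @export
hrf_double_gamma <- function(t, peak1 = 6, peak2 = 16,
                             undershoot_ratio = 1 / 6) {
  h <- stats::dgamma(t, shape = peak1, rate = 1) -
    undershoot_ratio * stats::dgamma(t, shape = peak2, rate = 1)
  h / max(h)
}

# circular Gaussian tuning bump, unit peak; width = SD in degrees
tuning_bump <- function(delta_deg, width) {
  exp(-0.5 * (wrap_angle(delta_deg) / width)^2)
}

#' Construct an ROI time-series object
#'
#' Container for a (trial x TR x voxel) activation array sampled on the
#' 750 ms TR grid, with per-trial run labels and a z-scoring flag.
#' Z-scoring, when applied, standardizes every voxel over all volumes of
#' each run (the concatenated TRs of that run's trials).
#'
#' @param data Numeric array `(n_trials, n_tr, n_voxels)`.
#' @param tr_onsets TR onsets in seconds relative to delay onset.
#' @param run_ids Integer vector of per-trial run labels.
#' @param trial_ids Integer vector of per-trial ids.
#' @param zscored Logical flag.
#' @param tr Repetition time, seconds (default 0.75).
#' @return An object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(data, tr_onsets, run_ids, trial_ids,
                           zscored = FALSE, tr = 0.75) {
  stopifnot(length(dim(data)) == 3,
            dim(data)[2] == length(tr_onsets),
            dim(data)[1] == length(run_ids),
            dim(data)[1] == length(trial_ids))
  structure(
    list(data = data, tr_onsets = tr_onsets, tr = tr,
         run_ids = run_ids, trial_ids = trial_ids, zscored = zscored),
    class = "roi_timeseries"
  )
}

#' @export
print.roi_timeseries <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<roi_timeseries> %d trials x %d TRs x %d voxels (TR %.0f ms, %szscored)\n",
    d[1], d[2], d[3], x$tr * 1000, if (x$zscored) "" else "not "
  ))
  invisible(x)
}

#' Z-score an ROI time series within runs
#'
#' Standardizes each voxel to mean 0, SD 1 across all volumes of each run,
#' matching the preprocessing applied before multivariate analysis.
#'
#' @param ts An [roi_timeseries()] object.
#' @return The z-scored `roi_timeseries`.
#' @export
zscore_runs <- function(ts) {
  d <- dim(ts$data)
  for (run in unique(ts$run_ids)) {
    idx <- which(ts$run_ids == run)
    # volumes of this run: (trials-in-run * TRs) x voxels
    flat <- matrix(aperm(ts$data[idx, , , drop = FALSE], c(2, 1, 3)),
                   nrow = length(idx) * d[2], ncol = d[3])
    mu <- colMeans(flat)
    sd <- apply(flat, 2, stats::sd) * sqrt((nrow(flat) - 1) / nrow(flat))
    sd[sd == 0] <- 1
    flat <- sweep(sweep(flat, 2, mu), 2, sd, "/")
    ts$data[idx, , ] <- aperm(array(flat, c(d[2], length(idx), d[3])),
                              c(2, 1, 3))
  }
  ts$zscored <- TRUE
  ts
}

#' Simulate BOLD-like ROI time series for a trial design
#'
#' Each voxel's noiseless response on a trial is a sustained target signal —
#' the voxel's circular-Gaussian tuning evaluated at the (possibly biased)
#' target angle, on for the encoding-plus-delay window — plus, on
#' distractor-present trials, a transient distractor-tuned response during
#' the 1 s distractor window. Neural boxcars are convolved with a
#' double-gamma hemodynamic kernel on a fine time grid, sampled at the
#' 750 ms TR onsets, degraded with i.i.d. Gaussian noise, and z-scored per
#' run.
#'
#' @param design Trial tibble for one participant ([generate_design()]).
#' @param pop Voxel population tibble ([generate_population()]).
#' @param noise_sd SD of the additive Gaussian noise per (TR, voxel), a.u.
#' @param neural_bias Trial-wise angular bias added to the encoded target
#'   angle, degrees; scalar or one value per trial.
#' @param distractor_gain Scalar multiplier on the distractor response.
#' @param target_suppression Fraction of the target drive transiently
#'   suppressed while the distractor is on screen (present trials with a
#'   nonzero `distractor_gain` only). Models the interference of jointly
#'   encoding the memorandum and the distractor in one population; 0
#'   disables it and recovers a pure additive signal.
#' @param hrf Function of time (seconds) returning the hemodynamic kernel.
#' @param tr_onsets TR grid, seconds relative to delay onset.
#' @param zscore If `TRUE` (default), z-score within runs.
#' @param ar_coef Optional lag-1 autocorrelation of the noise (default 0,
#'   i.e. white noise).
#' @param seed Integer seed.
#' @return An [roi_timeseries()] object.
#' @export
simulate_timeseries <- function(design, pop, noise_sd = 1, neural_bias = 0,
                                distractor_gain = 1,
                                target_suppression = 0.4,
                                hrf = hrf_double_gamma,
                                tr_onsets = seq(-3, 15, by = 0.75),
                                zscore = TRUE, ar_coef = 0, seed = NULL) {
  if (target_suppression < 0 || target_suppression > 1) {
    stop("`target_suppression` must lie in [0, 1]")
  }
  n_trials <- nrow(design)
  n_vox <- nrow(pop)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  if (length(neural_bias) == 1) neural_bias <- rep(neural_bias, n_trials)
  if (length(neural_bias) != n_trials) {
    stop("`neural_bias` must be a scalar or one value per trial")
  }
  if (!is.null(seed)) set.seed(seed)

  # neural boxcars on a fine grid, convolved once per distinct profile
  dt <- 0.25
  fine_t <- seq(min(tr_onsets), max(tr_onsets), by = dt)
  kern_t <- seq(0, 30, by = dt)
  kern <- hrf(kern_t)
  convolved <- function(on, off) {
    box <- as.numeric(fine_t >= on & fine_t < off)
    full <- stats::convolve(box, rev(kern), type = "open")[seq_along(fine_t)]
    full * dt
  }
  sample_tr <- function(sig) {
    sig[match(round(tr_onsets / dt), round(fine_t / dt))]
  }
  ev <- trial_event_times()
  h_target <- sample_tr(convolved(ev[["target"]], ev[["response"]]))
  h_dist <- sample_tr(convolved(ev[["distractor"]], ev[["distractor"]] + 1))
  # target drive lost to processing the distractor, same temporal profile
  # as the distractor response
  h_supp <- h_dist

  n_tr <- length(tr_onsets)
  data <- array(0, c(n_trials, n_tr, n_vox))
  present <- design$condition == "distractor_present"
  for (i in seq_len(n_trials)) {
    tune_t <- pop$gain_delay *
      tuning_bump(design$target_angle[i] + neural_bias[i] - pop$prf_angle,
                  pop$tuning_width)
    sig <- outer(h_target, tune_t)
    if (present[i] && distractor_gain != 0) {
      tune_d <- pop$gain_distractor *
        tuning_bump(design$distractor_angle[i] - pop$prf_angle,
                    pop$tuning_width)
      sig <- sig + distractor_gain * outer(h_dist, tune_d) -
        target_suppression * outer(h_supp, tune_t)
    }
    data[i, , ] <- sig
  }

  if (noise_sd > 0) {
    eps <- array(stats::rnorm(length(data), 0, noise_sd), dim(data))
    if (ar_coef != 0) {
      # AR(1) over the TR axis, stationary variance noise_sd^2
      eps <- eps * sqrt(1 - ar_coef^2)
      for (t in 2:n_tr) {
        eps[, t, ] <- ar_coef * eps[, t - 1, ] + eps[, t, ]
      }
      eps[, 1, ] <- eps[, 1, ] / sqrt(1 - ar_coef^2)
    }
    data <- data + eps
  }

  ts <- roi_timeseries(data, tr_onsets, design$run_id, design$trial_id)
  if (zscore) ts <- zscore_runs(ts)
  ts
}

#' Tidy an ROI time series into a long tibble
#'
#' @param x An [roi_timeseries()] object.
#' @param ... Unused.
#' @return A tibble with columns `trial_id`, `run_id`, `time`, `voxel`,
#'   `activation`.
#' @method tidy roi_timeseries
#' @export
tidy.roi_timeseries <- function(x, ...) {
  d <- dim(x$data)
  tibble::tibble(
    trial_id = rep(x$trial_ids, times = d[2] * d[3]),
    run_id = rep(x$run_ids, times = d[2] * d[3]),
    time = rep(rep(x$tr_onsets, each = d[1]), times = d[3]),
    voxel = rep(seq_len(d[3]), each = d[1] * d[2]),
    activation = as.vector(x$data)
  )
}
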