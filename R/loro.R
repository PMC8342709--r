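#' Leave-one-run-out cross-temporal generalization
#'
#' Using distractor-present trials only, estimates an encoding model at
#' each training timepoint (or epoch) from all runs but one, reconstructs
#' the held-out run at every test timepoint (or epoch), and cycles the
#' held-out run so every trial is tested exactly once. Cell values are the
#' mean target-aligned fidelity over all tested trials. With matched train
#' and test indices this reduces to ordinary leave-one-run-out decoding;
#' the off-diagonal PRE/POST cells diagnose stable vs morphed codes.
#'
#' @param ts An [roi_timeseries()] (all trials; present trials are
#'   selected internally).
#' @param trials Trial tibble matching `ts`.
#' @param basis A [channel_basis()].
#' @param mode `"epoch"` (default; PRE/DIST/POST) or `"timepoint"` (every
#'   TR).
#' @param epochs Epoch names used when `mode = "epoch"`.
#' @return A tibble of class `wm_generalization` with `train`, `test`,
#'   `fidelity`, `n_trials`.
#' @export
loro_generalization <- function(ts, trials, basis = channel_basis(),
                                mode = c("epoch", "timepoint"),
                                epochs = c("PRE", "DIST", "POST")) {
  mode <- match.arg(mode)
  stopifnot(nrow(trials) == dim(ts$data)[1])
  present <- which(trials$condition == "distractor_present")
  if (length(present) == 0) stop("no distractor-present trials")
  runs <- unique(ts$run_ids[present])
  if (length(runs) < 2) {
    stop("leave-one-run-out requires at least 2 runs with present trials")
  }

  # training/testing feature matrices per index: trials x voxels
  if (mode == "epoch") {
    index <- epochs
    feat <- lapply(epochs, function(e) epoch_average(ts, e)[present, ,
                                                            drop = FALSE])
  } else {
    index <- ts$tr_onsets
    feat <- lapply(seq_along(index), function(t) {
      b <- ts$data[present, t, , drop = FALSE]
      dim(b) <- c(length(present), dim(ts$data)[3])
      b
    })
  }
  angles <- trials$target_angle[present]
  run_of <- ts$run_ids[present]

  cells <- purrr::map(seq_along(index), function(i_trn) {
    fid_all <- vector("list", length(index))
    for (held in runs) {
      trn <- which(run_of != held)
      tst <- which(run_of == held)
      model <- estimate_weights(channel_matrix(angles[trn], basis),
                                feat[[i_trn]][trn, , drop = FALSE], basis)
      for (i_tst in seq_along(index)) {
        ch <- invert_channels(feat[[i_tst]][tst, , drop = FALSE], model)
        fid_all[[i_tst]] <- c(fid_all[[i_tst]],
                              fidelity_rows(ch, basis, angles[tst]))
      }
    }
    tibble::tibble(
      train = index[i_trn],
      test = index,
      fidelity = vapply(fid_all, mean, numeric(1)),
      n_trials = vapply(fid_all, length, integer(1))
    )
  })
  out <- dplyr::bind_rows(cells)
  class(out) <- c("wm_generalization", class(out))
  attr(out, "mode") <- mode
  out
}
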