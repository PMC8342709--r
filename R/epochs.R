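#' Delay-period epoch windows
#'
#' Default analysis epochs in seconds relative to delay onset, assuming a
#' ~4 s hemodynamic delay: PRE (before the distractor response reaches the
#' BOLD signal), DIST (during it), POST (after it), and TRAIN (the window
#' used to estimate encoding-model weights, exactly 9 TRs of 750 ms). TR
#' inclusion is half-open: a TR belongs to an epoch when its onset lies in
#' \[start, end).
#'
#' @return A tibble with columns `epoch`, `start`, `end`.
#' @export
epoch_windows <- function() {
  tibble::tibble(
    epoch = c("PRE", "DIST", "POST", "TRAIN"),
    start = c(3.75, 8.25, 10.50, 5.25),
    end   = c(5.25, 9.75, 12.00, 12.00)
  )
}

resolve_epoch <- function(epoch) {
  if (is.character(epoch)) {
    w <- epoch_windows()
    row <- w[w$epoch == epoch, ]
    if (nrow(row) != 1) {
      stop(sprintf("unknown epoch '%s'; use one of %s or a [start, end) pair",
                   epoch, paste(epoch_windows()$epoch, collapse = ", ")))
    }
    c(row$start, row$end)
  } else {
    stopifnot(is.numeric(epoch), length(epoch) == 2, epoch[1] < epoch[2])
    epoch
  }
}

#' Average an ROI time series over an epoch
#'
#' Means the activation over all TRs whose onsets fall in the half-open
#' window \[start, end); on the default grid the TRAIN epoch averages
#' exactly 9 TRs.
#'
#' @param ts An [roi_timeseries()] object.
#' @param epoch An epoch name (`"PRE"`, `"DIST"`, `"POST"`, `"TRAIN"`) or a
#'   numeric `c(start, end)` in seconds relative to delay onset.
#' @return A numeric matrix (trials x voxels).
#' @export
epoch_average <- function(ts, epoch = "TRAIN") {
  win <- resolve_epoch(epoch)
  sel <- which(ts$tr_onsets >= win[1] & ts$tr_onsets < win[2])
  if (length(sel) == 0) {
    stop(sprintf("epoch [%g, %g) contains no TR onsets", win[1], win[2]))
  }
  out <- apply(ts$data[, sel, , drop = FALSE], c(1, 3), mean)
  attr(out, "n_tr") <- length(sel)
  out
}

#' Train an encoding model on delay-period activation
#'
#' Convenience wrapper: averages the time series over the training window
#' (default the TRAIN epoch, 5.25-12 s, 9 TRs), builds the predicted
#' channel matrix from the trial target angles, and estimates weights.
#'
#' @param ts An [roi_timeseries()] for the training task.
#' @param angles Target polar angles, one per trial of `ts`.
#' @param basis A [channel_basis()].
#' @param window Training window (epoch name or `c(start, end)`).
#' @return An `encoding_model` (see [estimate_weights()]).
#' @export
train_encoding_model <- function(ts, angles, basis = channel_basis(),
                                 window = "TRAIN") {
  stopifnot(length(angles) == dim(ts$data)[1])
  b_trn <- epoch_average(ts, window)
  c_trn <- channel_matrix(angles, basis)
  estimate_weights(c_trn, b_trn, basis,
                   training = list(window = resolve_epoch(window),
                                   n_trials = length(angles)))
}
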