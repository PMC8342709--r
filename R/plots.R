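#' Plot a reconstruction over polar angle
#'
#' @param object A `wm_recon` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot wm_recon
#' @export
autoplot.wm_recon <- function(object, ...) {
  df <- tidy(object)
  # center the x axis on the aligned location for readability
  df$angle_c <- wrap_angle(df$angle)
  ggplot2::ggplot(df[order(df$angle_c), ],
                  ggplot2::aes(x = .data$angle_c, y = .data$activation)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(
      x = if (is.null(object$aligned_to)) "polar angle (deg)"
        else "angle relative to aligned location (deg)",
      y = "reconstruction activation (a.u.)") +
    ggplot2::theme_minimal()
}

#' Plot a cross-temporal generalization matrix
#'
#' @param object A `wm_generalization` tibble from [loro_generalization()].
#' @param ... Unused.
#' @return A ggplot heat map of fidelity by train and test index.
#' @method autoplot wm_generalization
#' @export
autoplot.wm_generalization <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$test),
                                       y = factor(.data$train),
                                       fill = .data$fidelity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "test", y = "train", fill = "fidelity") +
    ggplot2::theme_minimal()
}

#' Plot group fidelity time courses
#'
#' @param data Tibble with `time`, `fidelity`, optionally `sem` and a
#'   grouping column.
#' @param colour Optional name of a grouping column (string).
#' @return A ggplot of fidelity against time with a SEM ribbon when
#'   available.
#' @export
plot_fidelity_timecourse <- function(data, colour = NULL) {
  aes <- if (is.null(colour)) {
    ggplot2::aes(x = .data$time, y = .data$fidelity)
  } else {
    ggplot2::aes(x = .data$time, y = .data$fidelity,
                 colour = .data[[colour]], fill = .data[[colour]])
  }
  p <- ggplot2::ggplot(data, aes)
  if ("sem" %in% names(data)) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$fidelity - .data$sem,
                   ymax = .data$fidelity + .data$sem),
      alpha = 0.2, colour = NA)
  }
  p + ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "time from delay onset (s)", y = "fidelity (a.u.)") +
    ggplot2::theme_minimal()
}

#' Plot a staircase trace
#'
#' @param object A `staircase_result`.
#' @param ... Unused.
#' @return A ggplot of coherence across trials with the burn-in marked.
#' @method autoplot staircase_result
#' @export
autoplot.staircase_result <- function(object, ...) {
  burn <- floor(object$burn_in * nrow(object$trace))
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$trial, y = .data$coherence)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = burn, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "trial", y = "coherence",
                  title = sprintf("post-burn-in accuracy %.1f%%",
                                  100 * object$accuracy)) +
    ggplot2::theme_minimal()
}
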