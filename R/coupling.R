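#' Trial-wise neural-behavioral coupling analysis
#'
#' Tests whether trial-by-trial errors in the decoded memory representation
#' predict behavioral memory errors on near-distractor trials. Both error
#' signs are flipped by the side of the distractor so that positive means
#' toward the distractor. Per participant, a Pearson correlation is
#' computed across trials (clipped at 1 - 1e-10 in magnitude), converted
#' to a Fisher z, and the across-participant t on the z values is compared
#' one-tailed against a null built by shuffling the behavior-neural
#' pairing within each participant. A pooled quartile variant bins each
#' participant's trials into quartiles of decoding error, averages both
#' errors per bin, pools the bins across participants, and compares the
#' pooled Pearson r against a shuffle-before-binning null.
#'
#' @param data Tidy tibble with one row per usable trial:
#'   `participant_id`, `decoding_error`, `memory_error`, and (optionally)
#'   `relative_distractor_angle` for the toward-distractor sign flip.
#' @param n_perm Number of permutations (default 1000).
#' @param min_trials Minimum usable trials per participant (default 3).
#' @param seed Integer seed.
#' @return A list of class `wm_coupling`: `by_participant` (tibble with
#'   `participant_id`, `n`, `r`, `z`), `statistic` (group t on z), `p`
#'   (one-tailed), `quartile` (tibble of pooled bin means),
#'   `quartile_r`, `quartile_p`, `n_dropped` (trials with undefined
#'   decoded angles), `n_perm`.
#' @export
coupling_analysis <- function(data, n_perm = 1000, min_trials = 3,
                              seed = NULL) {
  stopifnot(all(c("participant_id", "decoding_error", "memory_error") %in%
                  names(data)))
  if (!is.null(seed)) set.seed(seed)

  n_dropped <- sum(is.na(data$decoding_error))
  if (n_dropped > 0) {
    message(sprintf("dropping %d trial(s) with undefined decoded angles",
                    n_dropped))
    data <- data[!is.na(data$decoding_error), ]
  }
  if ("relative_distractor_angle" %in% names(data)) {
    flip <- ifelse(data$relative_distractor_angle < 0, -1, 1)
    data$decoding_error <- data$decoding_error * flip
    data$memory_error <- data$memory_error * flip
  }
  parts <- split(data, data$participant_id)
  n_per <- vapply(parts, nrow, integer(1))
  if (any(n_per < min_trials)) {
    stop(sprintf("participants with fewer than %d usable trials: %s",
                 min_trials,
                 paste(names(parts)[n_per < min_trials], collapse = ", ")))
  }

  clip_r <- function(r) {
    r[is.na(r)] <- 0
    pmin(pmax(r, -1 + 1e-10), 1 - 1e-10)
  }
  fisher_z <- function(r) atanh(clip_r(r))
  part_r <- vapply(parts, function(d) {
    stats::cor(d$decoding_error, d$memory_error)
  }, numeric(1))
  obs_t <- one_sample_t(fisher_z(part_r))

  null_t <- vapply(seq_len(n_perm), function(i) {
    r <- vapply(parts, function(d) {
      stats::cor(d$decoding_error, sample(d$memory_error))
    }, numeric(1))
    one_sample_t(fisher_z(r))
  }, numeric(1))
  p <- perm_pvalue(obs_t, null_t, "one")

  # quartile-binned pooled correlation; bins are defined by the (fixed)
  # decoding errors, so under the shuffle-before-binning null only the
  # behavioral bin means change
  bins <- lapply(parts, function(d) dplyr::ntile(d$decoding_error, 4))
  x_means <- unlist(lapply(names(parts), function(p_id) {
    rowsum(parts[[p_id]]$decoding_error, bins[[p_id]]) /
      tabulate(bins[[p_id]], 4)[sort(unique(bins[[p_id]]))]
  }))
  y_means_for <- function(perm) {
    unlist(lapply(names(parts), function(p_id) {
      y <- parts[[p_id]]$memory_error
      if (perm) y <- y[sample.int(length(y))]
      rowsum(y, bins[[p_id]]) /
        tabulate(bins[[p_id]], 4)[sort(unique(bins[[p_id]]))]
    }))
  }
  y_means <- y_means_for(FALSE)
  q_r <- stats::cor(x_means, y_means)
  q_null <- vapply(seq_len(n_perm), function(i) {
    stats::cor(x_means, y_means_for(TRUE))
  }, numeric(1))
  q_p <- perm_pvalue(q_r, q_null, "one")
  pooled <- tibble::tibble(
    participant_id = rep(names(parts),
                         times = vapply(bins, function(b)
                           length(unique(b)), integer(1))),
    quartile = unlist(lapply(bins, function(b) sort(unique(b)))),
    decoding_error = x_means,
    memory_error = y_means
  )

  structure(
    list(
      by_participant = tibble::tibble(
        participant_id = names(parts), n = unname(n_per),
        r = unname(part_r), z = unname(fisher_z(part_r))),
      statistic = obs_t, p = p,
      quartile = pooled, quartile_r = q_r, quartile_p = q_p,
      n_dropped = n_dropped, n_perm = n_perm
    ),
    class = "wm_coupling"
  )
}

#' @export
print.wm_coupling <- function(x, ...) {
  cat(sprintf(
    "<wm_coupling> %d participants: mean r = %.3f, t(z) = %.2f, p = %.4g; quartile r = %.3f, p = %.4g (%d perms)\n",
    nrow(x$by_participant), mean(x$by_participant$r), x$statistic, x$p,
    x$quartile_r, x$quartile_p, x$n_perm
  ))
  invisible(x)
}

#' Tidy a coupling result
#'
#' @param x A `wm_coupling` object.
#' @param ... Unused.
#' @return The per-participant tibble of correlations and Fisher z values.
#' @method tidy wm_coupling
#' @export
tidy.wm_coupling <- function(x, ...) x$by_participant

#' One-row summary of a coupling result
#'
#' @param x A `wm_coupling` object.
#' @param ... Unused.
#' @return A one-row tibble with the group statistics.
#' @method glance wm_coupling
#' @export
glance.wm_coupling <- function(x, ...) {
  tibble::tibble(
    n_participants = nrow(x$by_participant),
    mean_r = mean(x$by_participant$r),
    statistic = x$statistic, p = x$p,
    quartile_r = x$quartile_r, quartile_p = x$quartile_p,
    n_dropped = x$n_dropped, n_perm = x$n_perm
  )
}
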