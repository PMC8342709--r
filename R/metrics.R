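#' Fidelity of an aligned reconstruction
#'
#' Projects the reconstruction onto the cosine of polar angle:
#' `F = mean(r(theta) * cos(theta))` over the uniform full-circle grid.
#' After aligning to the true stimulus angle, positive fidelity means the
#' reconstruction points at the stimulus; on a uniform grid the metric is
#' exactly invariant to any constant baseline added to `r`.
#'
#' @param recon An aligned [reconstruct()] object (see [align_recon()]).
#' @return Fidelity, a.u. (plain numeric).
#' @export
fidelity <- function(recon) {
  stopifnot(inherits(recon, "wm_recon"))
  if (is.null(recon$aligned_to)) {
    stop("reconstruction must be aligned (`align_recon()`) before fidelity")
  }
  check_uniform_grid(recon$grid)
  mean(recon$activation * cos_deg(recon$grid))
}

check_uniform_grid <- function(grid) {
  step <- diff(grid)
  if (length(grid) < 4 || any(abs(step - step[1]) > 1e-9) ||
      abs(grid[1]) > 1e-9 || abs(360 - (grid[length(grid)] + step[1])) > 1e-9) {
    stop("grid must be uniform and cover the full circle [0, 360)")
  }
  invisible(TRUE)
}

#' Decode the represented angle as the circular mean of a reconstruction
#'
#' Sums unit vectors at every grid angle weighted by the reconstruction
#' activation and takes the direction of the resultant:
#' `WM_est = atan2(sum r sin(theta), sum r cos(theta))`, mapped to
#' \[0, 360). When the resultant is numerically degenerate (flat or
#' antipodally symmetric reconstructions) the decoded angle is undefined
#' and returned as `NA` (never a silent 0).
#'
#' @param recon A [reconstruct()] object.
#' @param eps Relative threshold: the angle is undefined when the resultant
#'   length falls below `eps * sum(|r|)` (default 1e-9).
#' @return Decoded angle in \[0, 360) (or `NA` if undefined), with the
#'   resultant length attached as attribute `"resultant"`.
#' @export
decode_angle <- function(recon, eps = 1e-9) {
  stopifnot(inherits(recon, "wm_recon"))
  check_uniform_grid(recon$grid)
  r <- recon$activation
  s <- sum(r * sin_deg(recon$grid))
  c <- sum(r * cos_deg(recon$grid))
  len <- sqrt(s^2 + c^2)
  scale <- sum(abs(r))
  ang <- if (scale == 0 || len < eps * scale) {
    NA_real_
  } else {
    angle_mod360(atan2(s, c) * 180 / pi)
  }
  structure(ang, resultant = len)
}

#' Signed decoding error
#'
#' Wrapped difference between a decoded angle and the true angle, in
#' (-180, 180\] (the antipode maps to +180). Undefined decoded angles
#' propagate as `NA`.
#'
#' @param decoded Decoded angle, degrees (e.g. from [decode_angle()]).
#' @param truth True angle, degrees.
#' @return Signed error in degrees.
#' @export
decoding_error <- function(decoded, truth) {
  wrap_angle(as.numeric(decoded) - truth)
}

# ---- internal vectorized metric paths -------------------------------------
# Fidelity of many channel-response rows at once without materialising
# every reconstruction: with grid basis G (g x k) and per-row reference
# angles ref, F_i = mean_g [ (C G')_ig * cos(grid_g - ref_i) ].
fidelity_rows <- function(channels, basis, ref, grid_step = 1) {
  grid <- seq(0, 360 - grid_step, by = grid_step)
  r <- as.matrix(channels) %*% t(channel_matrix(grid, basis)) # rows x grid
  cosmat <- cos_deg(outer(ref, grid, function(a, g) g - a))
  rowMeans(r * cosmat)
}

# circular-mean decode of many rows; returns angles in [0, 360) with NA
# for degenerate resultants
decode_rows <- function(channels, basis, grid_step = 1, eps = 1e-9) {
  grid <- seq(0, 360 - grid_step, by = grid_step)
  r <- as.matrix(channels) %*% t(channel_matrix(grid, basis))
  s <- r %*% sin_deg(grid)
  c <- r %*% cos_deg(grid)
  len <- sqrt(s^2 + c^2)
  ang <- angle_mod360(atan2(s, c) * 180 / pi)
  ang[len < eps * rowSums(abs(r))] <- NA_real_
  drop(ang)
}
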