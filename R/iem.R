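#' Define a polar-angle channel basis
#'
#' The encoding model describes each voxel as a linear combination of `k`
#' smooth information channels tuned to polar angle. Each channel is a
#' rectified raised-cosine filter: with wrapped distance
#' `d = |theta - psi_i|` in \[0, 180\] and size constant `s`, the channel
#' response is `0.5 + 0.5 * cos(180 * d / (2 s))^p` for `d < s` and 0
#' otherwise (cosine argument in degrees). By default the exponent applies
#' to the cosine alone (`"power_on_cosine"`); `"power_on_sum"` raises the
#' whole half-raised cosine to the power instead, giving a narrower,
#' baseline-free bump. In both modes the channel equals 1 at its own
#' center.
#'
#' @param n_channels Number of channels `k` (default 8), evenly spaced.
#' @param size_constant Size constant `s`, degrees (default 180).
#' @param exponent Positive integer exponent (default 8).
#' @param mode `"power_on_cosine"` (default) or `"power_on_sum"`.
#' @param centers Optional explicit channel centers, degrees; must be
#'   distinct modulo 360.
#' @return An object of class `channel_basis`.
#' @examples
#' b <- channel_basis()
#' channel_response(90, b)
#' @export
channel_basis <- function(n_channels = 8, size_constant = 180, exponent = 8,
                          mode = c("power_on_cosine", "power_on_sum"),
                          centers = NULL) {
  mode <- match.arg(mode)
  if (is.null(centers)) {
    centers <- seq(0, 360 - 360 / n_channels, by = 360 / n_channels)
  }
  if (anyDuplicated(angle_mod360(centers))) {
    stop("channel centers must be distinct modulo 360")
  }
  if (size_constant <= 0) stop("`size_constant` must be positive")
  if (exponent < 1) stop("`exponent` must be a positive integer")
  structure(
    list(centers = angle_mod360(centers), size_constant = size_constant,
         exponent = exponent, mode = mode),
    class = "channel_basis"
  )
}

#' @export
print.channel_basis <- function(x, ...) {
  cat(sprintf(
    "<channel_basis> %d channels, s = %g deg, exponent %d (%s)\n",
    length(x$centers), x$size_constant, x$exponent, x$mode
  ))
  invisible(x)
}

#' Evaluate channel responses to a single polar angle
#'
#' @param theta Polar angle, degrees (finite scalar).
#' @param basis A [channel_basis()].
#' @return Numeric vector of length `k` with the response of every channel.
#' @export
channel_response <- function(theta, basis) {
  stopifnot(length(theta) == 1, is.finite(theta))
  drop(channel_matrix(theta, basis))
}

#' Predicted channel-response matrix for a set of angles
#'
#' Row `i` holds the channel responses to `angles[i]`; this is the design
#' matrix `C` (n trials x k channels) of the forward model `B = C W`.
#'
#' @param angles Polar angles, degrees.
#' @param basis A [channel_basis()].
#' @return Numeric matrix `(length(angles), k)`.
#' @export
channel_matrix <- function(angles, basis) {
  stopifnot(length(angles) >= 1, all(is.finite(angles)))
  d <- abs(wrap_angle(outer(angles, basis$centers, "-")))
  u <- cos_deg(180 * d / (2 * basis$size_constant))
  f <- switch(basis$mode,
    power_on_cosine = 0.5 + 0.5 * u^basis$exponent,
    power_on_sum = (0.5 + 0.5 * u)^basis$exponent
  )
  f[d >= basis$size_constant] <- 0
  dimnames(f) <- NULL
  f
}

# reciprocal-condition guard for the model's two matrix inversions
check_conditioning <- function(m, what, tol = 1e-10) {
  sv <- svd(m, nu = 0, nv = 0)$d
  if (sv[1] == 0 || min(sv) / max(sv) < tol) {
    stop(sprintf(
      "%s is rank-deficient or ill-conditioned (reciprocal condition number %.2e < %.0e)",
      what, if (sv[1] == 0) 0 else min(sv) / max(sv), tol
    ), call. = FALSE)
  }
  invisible(TRUE)
}

#' Estimate encoding-model weights by ordinary least squares
#'
#' Solves the forward model `B_trn = C_trn W` for the channel-to-voxel
#' weight matrix: `What = (C'C)^-1 C' B_trn`, the column-wise OLS solution.
#' The training design must have at least as many trials as channels and a
#' well-conditioned channel matrix.
#'
#' @param c_trn Predicted channel matrix, `n x k` ([channel_matrix()]).
#' @param b_trn Training activation matrix, `n x m` (trials x voxels).
#' @param basis The [channel_basis()] that generated `c_trn`.
#' @param training Optional metadata list stored with the model.
#' @return An object of class `encoding_model` with elements `basis`,
#'   `weights` (`k x m`), and `training`.
#' @export
estimate_weights <- function(c_trn, b_trn, basis, training = list()) {
  c_trn <- as.matrix(c_trn)
  b_trn <- as.matrix(b_trn)
  if (nrow(c_trn) != nrow(b_trn)) {
    stop("`c_trn` and `b_trn` must have the same number of training trials")
  }
  if (nrow(c_trn) < ncol(c_trn)) {
    stop("underdetermined system: fewer training trials than channels")
  }
  check_conditioning(c_trn, "training channel matrix `C_trn`")
  w <- solve(crossprod(c_trn), crossprod(c_trn, b_trn))
  if (!all(is.finite(w))) stop("non-finite weights estimated")
  structure(
    list(basis = basis, weights = w, training = training),
    class = "encoding_model"
  )
}

#' @export
print.encoding_model <- function(x, ...) {
  cat(sprintf("<encoding_model> %d channels x %d voxels\n",
              nrow(x$weights), ncol(x$weights)))
  invisible(x)
}

#' Invert the encoding model onto test activation patterns
#'
#' Maps measured voxel patterns back into channel space:
#' `C_tst = B_tst W' (W W')^-1`. Requires at least as many voxels as
#' channels and a well-conditioned `W W'`.
#'
#' @param b_tst Test activation matrix, `t x m` (rows are timepoints,
#'   trials, or trial-epoch averages).
#' @param model An [estimate_weights()] model.
#' @return Estimated channel responses, `t x k`.
#' @export
invert_channels <- function(b_tst, model) {
  b_tst <- as.matrix(b_tst)
  w <- model$weights
  if (ncol(b_tst) != ncol(w)) {
    stop("voxel count of `b_tst` does not match the encoding model")
  }
  if (ncol(w) < nrow(w)) {
    stop("inversion requires at least as many voxels as channels")
  }
  wwt <- tcrossprod(w)
  check_conditioning(wwt, "`W W'`")
  b_tst %*% t(w) %*% solve(wwt)
}

#' Reconstruct activation over polar angle from channel responses
#'
#' The reconstruction is the sum of all channel sensitivity profiles, each
#' weighted by its estimated channel response, evaluated on a uniform
#' full-circle grid (default 1 degree spacing).
#'
#' @param channels Numeric `k`-vector of channel responses.
#' @param basis A [channel_basis()] (or an `encoding_model`, whose basis is
#'   used).
#' @param grid_step Grid spacing, degrees; must divide 360.
#' @return An object of class `wm_recon` with `grid` (degrees in
#'   \[0, 360)), `activation`, and `aligned_to` (NULL until [align_recon()]
#'   is applied).
#' @export
reconstruct <- function(channels, basis, grid_step = 1) {
  if (inherits(basis, "encoding_model")) basis <- basis$basis
  if (360 %% grid_step != 0) stop("`grid_step` must divide 360")
  grid <- seq(0, 360 - grid_step, by = grid_step)
  act <- drop(channel_matrix(grid, basis) %*% as.numeric(channels))
  structure(list(grid = grid, activation = act, aligned_to = NULL),
            class = "wm_recon")
}

#' @export
print.wm_recon <- function(x, ...) {
  cat(sprintf(
    "<wm_recon> %d grid points, peak %.3f at %g deg%s\n",
    length(x$grid), max(x$activation), x$grid[which.max(x$activation)],
    if (is.null(x$aligned_to)) "" else sprintf(" (aligned to %g deg)",
                                               x$aligned_to)
  ))
  invisible(x)
}

#' Circularly align a reconstruction to a reference angle
#'
#' Shifts the reconstruction so that the activation at the reference angle
#' appears at 0 degrees; the reference is snapped to the nearest grid
#' point. Total activation is preserved.
#'
#' @param recon A [reconstruct()] object.
#' @param reference Reference angle, degrees.
#' @return The aligned `wm_recon` with `aligned_to` set.
#' @export
align_recon <- function(recon, reference) {
  stopifnot(inherits(recon, "wm_recon"), is.finite(reference))
  step <- recon$grid[2] - recon$grid[1]
  ref_idx <- (round(angle_mod360(reference) / step)) %% length(recon$grid)
  n <- length(recon$grid)
  idx <- ((seq_len(n) - 1 + ref_idx) %% n) + 1
  recon$activation <- recon$activation[idx]
  recon$aligned_to <- angle_mod360(
    if (is.null(recon$aligned_to)) ref_idx * step
    else recon$aligned_to + ref_idx * step
  )
  recon
}

#' Tidy a reconstruction into a tibble
#'
#' @param x A `wm_recon` object.
#' @param ... Unused.
#' @return A tibble with `angle` and `activation`.
#' @method tidy wm_recon
#' @export
tidy.wm_recon <- function(x, ...) {
  tibble::tibble(angle = x$grid, activation = x$activation)
}

#' Tidy an encoding model's weights
#'
#' @param x An `encoding_model`.
#' @param ... Unused.
#' @return A tibble with `channel`, `center`, `voxel`, `weight`.
#' @method tidy encoding_model
#' @export
tidy.encoding_model <- function(x, ...) {
  k <- nrow(x$weights)
  m <- ncol(x$weights)
  tibble::tibble(
    channel = rep(seq_len(k), times = m),
    center = rep(x$basis$centers, times = m),
    voxel = rep(seq_len(m), each = k),
    weight = as.vector(x$weights)
  )
}

#' One-line summary of an encoding model
#'
#' @param x An `encoding_model`.
#' @param ... Unused.
#' @return A one-row tibble with `n_channels`, `n_voxels`, `size_constant`,
#'   `exponent`, `mode`.
#' @method glance encoding_model
#' @export
glance.encoding_model <- function(x, ...) {
  tibble::tibble(
    n_channels = nrow(x$weights), n_voxels = ncol(x$weights),
    size_constant = x$basis$size_constant, exponent = x$basis$exponent,
    mode = x$basis$mode
  )
}
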