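#' Generate a synthetic spatially tuned voxel population
#'
#' Assigns ground-truth population-receptive-field (pRF) parameters to a set
#' of voxels: preferred polar angle uniform on \[0, 360), eccentricity and
#' pRF size within stated ranges, simulated variance explained (`r2`), an
#' angular tuning width used by the BOLD simulator, and per-voxel response
#' gains for the sustained delay signal and the transient distractor
#' response. The simulator owns the ground truth that, with real data, a
#' retinotopic-mapping fit would provide.
#'
#' @param n_voxels Number of voxels (>= 1).
#' @param seed Integer seed.
#' @param width_range Range of angular tuning widths (SD of the circular
#'   Gaussian tuning curve), degrees.
#' @param r2_range Range of simulated variance explained, fractions in
#'   \[0, 1\].
#' @param ecc_range Range of pRF eccentricities, degrees of visual angle.
#' @param size_range Range of pRF sizes, degrees.
#' @param gain_range Range of per-voxel delay-period gains (a.u.); the
#'   distractor gain is drawn from the same range independently.
#' @return A tibble with one row per voxel: `voxel`, `prf_angle`, `prf_ecc`,
#'   `prf_size`, `r2`, `tuning_width`, `gain_delay`, `gain_distractor`.
#' @examples
#' pop <- generate_population(50, seed = 1)
#' range(pop$prf_ecc)
#' @export
generate_population <- function(n_voxels, seed = NULL,
                                width_range = c(25, 50),
                                r2_range = c(0.1, 0.8),
                                ecc_range = c(2, 15),
                                size_range = c(1, 6),
                                gain_range = c(0.5, 1.5)) {
  if (n_voxels < 1) stop("`n_voxels` must be a positive count")
  for (rng in list(width_range, r2_range, ecc_range, size_range, gain_range)) {
    if (length(rng) != 2 || any(is.na(rng)) || rng[2] < rng[1]) {
      stop("ranges must be length-2 non-decreasing numeric vectors")
    }
  }
  if (r2_range[1] < 0 || r2_range[2] > 1) stop("`r2_range` must lie in [0, 1]")
  if (width_range[1] <= 0) stop("tuning widths must be positive")
  if (ecc_range[1] < 0) stop("eccentricities must be non-negative")
  if (!is.null(seed)) set.seed(seed)

  tibble::tibble(
    voxel = seq_len(n_voxels),
    prf_angle = stats::runif(n_voxels, 0, 360),
    prf_ecc = stats::runif(n_voxels, ecc_range[1], ecc_range[2]),
    prf_size = stats::runif(n_voxels, size_range[1], size_range[2]),
    r2 = stats::runif(n_voxels, r2_range[1], r2_range[2]),
    tuning_width = stats::runif(n_voxels, width_range[1], width_range[2]),
    gain_delay = stats::runif(n_voxels, gain_range[1], gain_range[2]),
    gain_distractor = stats::runif(n_voxels, gain_range[1], gain_range[2])
  )
}
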