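#' Wrap angular differences to (-180, 180]
#'
#' All angular arithmetic in the package works in degrees on the half-open
#' circle \[0, 360). Differences between angles are reported wrapped to the
#' signed interval (-180, 180], with the antipode mapped to +180 by
#' convention.
#'
#' @param x Numeric vector of angles or angular differences, degrees.
#' @return Numeric vector wrapped to (-180, 180].
#' @examples
#' wrap_angle(c(350, 370, -180, 180))
#' @export
wrap_angle <- function(x) {
  w <- (x + 180) %% 360 - 180
  # the boundary -180 is the same point as +180; keep the positive label
  w[!is.na(w) & w == -180] <- 180
  w
}

#' Map angles to the half-open circle \[0, 360)
#'
#' @param x Numeric vector of angles, degrees.
#' @return Angles reduced modulo 360 into \[0, 360).
#' @export
angle_mod360 <- function(x) x %% 360

# cosine/sine with degree arguments
cos_deg <- function(x) cospi(x / 180)
sin_deg <- function(x) sinpi(x / 180)

# absolute circular distance in [0, 180]
circ_dist <- function(a, b) abs(wrap_angle(a - b))
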