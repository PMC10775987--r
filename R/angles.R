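#' Angle helpers
#'
#' All angles in this package are in degrees, measured counterclockwise from
#' the positive x-axis (east). Turns are counterclockwise-positive and
#' normalized to (-180, 180]; absolute directions to [0, 360).
#'
#' @param theta numeric vector of angles in degrees.
#' @return `wrap180()` returns angles in (-180, 180]; `wrap360()` in [0, 360).
#' @name angles
NULL

#' @rdname angles
#' @export
wrap180 <- function(theta) {
  out <- theta %% 360
  out[out > 180] <- out[out > 180] - 360
  # map -180 (can arise from negative inputs on the boundary) to +180
  out[out <= -180] <- out[out <= -180] + 360
  out
}

#' @rdname angles
#' @export
wrap360 <- function(theta) theta %% 360

deg2rad <- function(theta) theta * pi / 180
rad2deg <- function(theta) theta * 180 / pi

## direction of the vector (dx, dy), degrees CCW from east in [0, 360)
vec_dir <- function(dx, dy) wrap360(rad2deg(atan2(dy, dx)))
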