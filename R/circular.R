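#' Wrap an orientation into [0, 180)
#'
#' Orientations are axial: a bar tilted at 185 degrees is the same bar as one
#' tilted at 5 degrees. All orientation columns in a trial table live on
#' `[0, 180)`.
#'
#' @param x Numeric vector of angles in degrees.
#' @return Numeric vector in `[0, 180)`.
#' @export
#' @examples
#' wrap_orientation(c(-10, 185, 90))
wrap_orientation <- function(x) {
  x %% 180
}

#' Signed circular difference between two orientations
#'
#' Computes `a - b` on the 180-degree-periodic orientation circle, wrapped to
#' the interval `(-90, 90]`. This is the quantity used throughout for
#' adjustment errors (response minus stimulus) and for the serial-dependence
#' predictors delta-S and delta-R (previous stimulus/response minus current
#' stimulus). Values landing exactly on the boundary are assigned +90.
#'
#' @param a,b Numeric vectors of orientations in degrees.
#' @return Signed difference in degrees, in `(-90, 90]`.
#' @export
#' @examples
#' wrap_delta(170, 10)  # -20, not 160
#' wrap_delta(0, 95)    # +85, not -95
wrap_delta <- function(a, b) {
  d <- (a - b) %% 180
  ifelse(d > 90, d - 180, d)
}

# internal: wrap an already-formed difference to (-90, 90]
.wrap90 <- function(x) {
  d <- x %% 180
  ifelse(d > 90, d - 180, d)
}

.deg2rad <- function(x) x * pi / 180
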