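#' Normalize angles to (-180, 180] degrees
#'
#' Body-frame light bearings use the signed convention: 0 deg is light
#' arriving from directly anterior, +/-180 deg from directly posterior,
#' positive values place the source on the animal's right.
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector in (-180, 180].
#' @export
#' @examples
#' wrap_signed(c(190, -180, 360))
wrap_signed <- function(x) {
  r <- (x + 180) %% 360 - 180
  r[r == -180] <- 180
  r
}

#' Normalize angles to [0, 360) degrees
#'
#' Exit bearings and arena-frame bearings use the compass-style convention:
#' 0 deg points at the light source (or arena north), increasing clockwise.
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector in [0, 360).
#' @export
wrap_circle <- function(x) x %% 360

# degree-based trig; interfaces carry degrees, radians only inside trig calls
sin_deg <- function(x) sinpi(x / 180)
cos_deg <- function(x) cospi(x / 180)
deg <- function(rad) rad * 180 / pi
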