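#' Eye geometry of a two-eyed planarian
#'
#' The paired pigment-cup eyes sit obliquely on the head, each rotated by
#' the obliqueness angle beta away from the anterior-posterior axis, so the
#' two monocular fields overlap on the anterior side in a *binocular field*
#' of width `bf = 2 * beta`. In the clamped-sine input model each eye's
#' monocular field spans a 180 deg half-plane; the measured morphometric
#' monocular field `alpha` (slightly under 180 deg in real animals) is used
#' only by [posterior_blind_field()].
#'
#' @param binocular_field width of the binocular field `bf` in degrees;
#'   must satisfy `0 <= bf < 180`. Defaults to 40, the species value used
#'   throughout for *Dugesia japonica* (use 60 for *Schmidtea mediterranea*).
#' @param monocular_field optional morphometric monocular field `alpha` in
#'   degrees, in (90, 180].
#' @return an object of class `eye_geometry` with fields `binocular_field`,
#'   `obliqueness` (`beta = bf / 2`) and `monocular_field` (or `NA`).
#' @seealso [eye_inputs()], [front_blind_half_angle()], [response_band()]
#' @export
#' @examples
#' eye_geometry(40)
eye_geometry <- function(binocular_field = 40, monocular_field = NULL) {
  stopifnot(is.numeric(binocular_field), length(binocular_field) == 1L,
            is.finite(binocular_field))
  if (binocular_field < 0 || binocular_field >= 180)
    stop("binocular_field must lie in [0, 180)")
  if (!is.null(monocular_field)) {
    stopifnot(is.numeric(monocular_field), length(monocular_field) == 1L)
    if (monocular_field <= 90 || monocular_field > 180)
      stop("monocular_field must lie in (90, 180]")
  }
  structure(
    list(binocular_field = binocular_field,
         obliqueness = binocular_field / 2,
         monocular_field = if (is.null(monocular_field)) NA_real_ else monocular_field),
    class = "eye_geometry")
}

#' @export
print.eye_geometry <- function(x, ...) {
  cat("Eye geometry: binocular field", x$binocular_field,
      "deg (obliqueness", x$obliqueness, "deg)")
  if (!is.na(x$monocular_field))
    cat(", monocular field", x$monocular_field, "deg")
  cat("\n")
  invisible(x)
}

as_eye_geometry <- function(geom) {
  if (inherits(geom, "eye_geometry")) geom else eye_geometry(geom)
}

#' Clamped-sine light inputs to the left and right eye
#'
#' The light input to each eye is modelled as the illuminated fraction of a
#' semicircular pigment-cup: `L(theta) = -sin(theta - bf/2)` and
#' `R(theta) = sin(theta + bf/2)`, with negative values clamped to zero
#' (an eye shielded from the light receives no input) and a maximum
#' attainable input of 1.
#'
#' @param theta light bearing(s) in degrees relative to the body axis,
#'   normalized with [wrap_signed()]; positive = source on the right.
#' @param geom an [eye_geometry()] object (or a bare `bf` value in degrees).
#' @return a numeric matrix with one row per bearing and columns
#'   `left`, `right`, both in `[0, 1]`.
#' @export
#' @examples
#' eye_inputs(130, eye_geometry(40))   # right eye at exactly 0.5
eye_inputs <- function(theta, geom = eye_geometry()) {
  geom <- as_eye_geometry(geom)
  theta <- wrap_signed(theta)
  b <- geom$obliqueness
  left  <- pmin(1, pmax(0, -sin_deg(theta - b)))
  right <- pmin(1, pmax(0,  sin_deg(theta + b)))
  cbind(left = left, right = right)
}

#' Signed difference between right- and left-eye inputs
#'
#' Returns `R(theta) - L(theta)`; the turning rule compares its absolute
#' value against the response threshold. An odd function of `theta`.
#'
#' @inheritParams eye_inputs
#' @return numeric vector of signed input differences.
#' @export
input_difference <- function(theta, geom = eye_geometry()) {
  inp <- eye_inputs(theta, geom)
  unname(inp[, "right"] - inp[, "left"])
}

#' Largest attainable left-right input difference
#'
#' For `bf < 90` the monocular zone reaches a full input of 1 against a dark
#' contralateral eye; for wider binocular fields the eyes never look far
#' enough apart and the maximum is `sin(bf)`.
#'
#' @inheritParams eye_inputs
#' @return scalar maximum of `|R - L|` over all bearings.
#' @export
max_input_difference <- function(geom = eye_geometry()) {
  geom <- as_eye_geometry(geom)
  bf <- geom$binocular_field
  if (bf < 90) 1 else sin_deg(bf)
}

#' Half-angle of the front blind-like spot
#'
#' The front blind-like spot is the anterior sector in which the left-right
#' input difference stays at or below the response threshold, so the light
#' direction cannot be discriminated even though both eyes are lit. This
#' returns the smallest positive bearing at which `|R - L|` reaches `tau`.
#'
#' In the binocular zone (`theta < bf/2`) the difference is
#' `2 * cos(bf/2) * sin(theta)`; past it the shaded eye clamps to zero and
#' the difference is `sin(theta + bf/2)`. The crossing falls in the
#' monocular zone when `asin(tau) > bf` (in degrees), giving
#' `asin(tau) - bf/2`; otherwise it is `asin(tau / (2 cos(bf/2)))`.
#'
#' @inheritParams eye_inputs
#' @param tau response threshold in (0, 1).
#' @return half-angle in degrees.
#' @export
#' @examples
#' front_blind_half_angle(eye_geometry(40), 0.5)   # ~15.43 deg
front_blind_half_angle <- function(geom = eye_geometry(), tau = 0.5) {
  geom <- as_eye_geometry(geom)
  stopifnot(is.numeric(tau), length(tau) == 1L, tau > 0, tau < 1)
  if (tau > max_input_difference(geom))
    stop("tau exceeds the maximum attainable input difference for this binocular field; ",
         "no threshold crossing exists")
  bf <- geom$binocular_field
  asin_tau <- deg(asin(tau))
  if (asin_tau > bf) {
    asin_tau - bf / 2
  } else {
    deg(asin(tau / (2 * cos_deg(bf / 2))))
  }
}

#' Response band of light bearings that trigger a turn
#'
#' The contiguous interval of positive bearings over which `|R - L|`
#' exceeds the response threshold; light arriving from inside this band (or
#' its mirror image) triggers avoidance turning. The upper edge,
#' `180 - asin(tau) - bf/2`, is where the lit eye's input decays back to
#' `tau` on the way into the posterior blind field.
#'
#' @inheritParams front_blind_half_angle
#' @return named numeric vector `c(lower, upper)` in degrees.
#' @export
#' @examples
#' response_band(eye_geometry(40), 0.5)   # c(15.43, 130)
response_band <- function(geom = eye_geometry(), tau = 0.5) {
  geom <- as_eye_geometry(geom)
  lower <- front_blind_half_angle(geom, tau)
  upper <- 180 - deg(asin(tau)) - geom$binocular_field / 2
  c(lower = lower, upper = upper)
}

#' Morphometric posterior blind field
#'
#' Width of the posterior sector visible to neither eye, computed from the
#' measured monocular field `alpha` and obliqueness `beta` as
#' `2 * (180 - alpha + beta)`. This is a morphometric helper independent of
#' the sine input model (which implicitly assumes `alpha = 180`).
#'
#' @inheritParams eye_inputs
#' @return blind-field width in degrees.
#' @export
#' @examples
#' posterior_blind_field(eye_geometry(2 * 19.4, monocular_field = 172.6))
posterior_blind_field <- function(geom) {
  geom <- as_eye_geometry(geom)
  if (is.na(geom$monocular_field))
    stop("monocular_field (alpha) is required for the posterior blind field")
  2 * (180 - geom$monocular_field + geom$obliqueness)
}
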