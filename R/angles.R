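#' Wrap an angle to the interval [-pi, pi)
#'
#' All angles in the package live on the half-open interval `[-pi, pi)` with
#' the convention 0 = east, pi/2 = north, pi (== -pi) = west, -pi/2 = south.
#' A single wrapping convention avoids double-counting the seam in histograms.
#'
#' @param theta numeric vector of angles in radians (any finite value).
#' @return numeric vector of the same length, each element in `[-pi, pi)` and
#'   congruent to the input modulo `2*pi`.
#' @examples
#' wrap_angle(3 * pi)       # -pi
#' wrap_angle(-pi - 0.1)    # pi - 0.1
#' @export
wrap_angle <- function(theta) {
  if (!is.numeric(theta) || anyNA(theta) || any(!is.finite(theta)))
    stop("'theta' must be finite numeric", call. = FALSE)
  ((theta + pi) %% (2 * pi)) - pi
}

#' Attraction map of the circle (tan-half-angle link)
#'
#' The smooth circle map
#' \deqn{M(\theta; \alpha, w) = \alpha + 2\arctan\{w \tan((\theta-\alpha)/2)\}}
#' underlying the circular auto-regression: it pulls the previous heading
#' `theta` toward the focal direction `alpha` with strength controlled by the
#' regression coefficient `w`. `w = 1` is the identity (correlated random
#' walk), `w = 0` collapses every angle onto `alpha`, and `w < 0` reflects
#' across `alpha` (reciprocating, zigzag movement). The map is continuous on
#' the whole circle: at the antipode `theta = alpha - pi` the value is taken
#' as the analytic limit `alpha + pi * sign(w)` rather than evaluating
#' `tan(pi/2)`.
#'
#' @param theta angle(s) to transform, radians.
#' @param alpha focal direction, radians (recycled against `theta`).
#' @param w regression coefficient; any finite real (negative, zero and
#'   values above 1 are all meaningful).
#'
#' Note an exact aliasing: the map has fixed points at both `alpha` and its
#' antipode, and `attract(theta, alpha, w)` equals
#' `attract(theta, alpha + pi, 1/w)` for every `w != 0`. Fits with a free
#' focal direction are therefore reported in the canonical representation
#' with `|w| <= 1`.
#' @return wrapped angle(s) `M(theta; alpha, w)`.
#' @seealso [attract_inverse()]
#' @examples
#' attract(pi / 2, 0, 0.5)  # 2 * atan(0.5) = 0.9273
#' attract(1.3, 1.3, 0.7)   # fixed point: 1.3
#' @export
attract <- function(theta, alpha, w) {
  stopifnot(is.numeric(w), all(is.finite(w)))
  d <- wrap_angle(wrap_angle(theta) - wrap_angle(alpha))
  out <- 2 * atan(w * tan(d / 2))
  anti <- d == -pi
  if (any(anti)) {
    ww <- rep_len(w, length(d))
    out[anti] <- pi * sign(ww[anti])
  }
  wrap_angle(alpha + out)
}

#' Inverse of the attraction map
#'
#' Solves `attract(x, alpha, w) == y` for `x`. Defined for every `w != 0`
#' (the collapsed map `w == 0` is not invertible).
#'
#' @inheritParams attract
#' @param y angle(s) in the image of the map.
#' @return wrapped angle(s) `x` with `attract(x, alpha, w) == y` on the circle.
#' @export
attract_inverse <- function(y, alpha, w) {
  stopifnot(is.numeric(w), all(is.finite(w)))
  if (any(w == 0)) stop("attraction map with w = 0 is not invertible", call. = FALSE)
  d <- wrap_angle(wrap_angle(y) - wrap_angle(alpha))
  out <- 2 * atan(tan(d / 2) / w)
  anti <- d == -pi
  if (any(anti)) {
    ww <- rep_len(w, length(d))
    out[anti] <- pi * sign(ww[anti])
  }
  wrap_angle(alpha + out)
}

## circular mean of a sample of angles
circ_mean <- function(x) atan2(mean(sin(x)), mean(cos(x)))

## mean resultant length
circ_rbar <- function(x) sqrt(mean(cos(x))^2 + mean(sin(x))^2)

## moment estimate of a von Mises concentration from a sample of angles
## (Fisher's piecewise approximation), clamped to a sane range for use as
## an optimisation start value
est_kappa <- function(x) {
  rb <- circ_rbar(x)
  k <- if (rb < 0.53) 2 * rb + rb^3 + 5 * rb^5 / 6
  else if (rb < 0.85) -0.4 + 1.39 * rb + 0.43 / (1 - rb)
  else 1 / (rb^3 - 4 * rb^2 + 3 * rb)
  min(max(k, 0.05), 500)
}
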