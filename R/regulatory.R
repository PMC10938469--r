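#' Sigmoidal regulatory function
#'
#' The saturating response \eqn{S(x, u) = (x-u)^2 / (a + (x-u)^2)} used for
#' the auxin--growth coupling, the red:far-red production switch, and the
#' light-dependent degradation term.  `u` is the translational value (the
#' input level at which the response starts) and `a` the shape constant
#' controlling steepness.  With `clamp = TRUE` (the model default) the
#' difference `x - u` is replaced by `max(x - u, 0)`, so the response is zero
#' at or below the translational value and monotone increasing above it;
#' without clamping the printed form is symmetric about `u`.
#'
#' @param x input value (concentration, light intensity, or signal ratio).
#' @param u translational value, same units as `x`.
#' @param a positive shape constant (units of `x` squared).
#' @param clamp replace `x - u` by `max(x - u, 0)` before squaring.
#' @return Response in `[0, 1)`.
#' @examples
#' sigmoid(2, 1, 1)        # half saturation: (x-u)^2 == a
#' sigmoid(0.5, 1, 1)      # clamped: zero below u
#' @export
sigmoid <- function(x, u, a, clamp = TRUE) {
  if (!is.numeric(a) || any(a <= 0)) {
    stop("`a` must be a positive shape constant", call. = FALSE)
  }
  d <- x - u
  if (clamp) d <- pmax(d, 0)
  d2 <- d * d
  d2 / (a + d2)
}

#' Monod (hyperbolic) regulatory function
#'
#' The saturating response \eqn{M(x, u) = (x-u) / (b + (x-u))} used for the
#' cumulative-light (cotyledon size) dependence of auxin input.  `b` is the
#' half-saturation constant: the response is 0.5 when `x - u == b`.
#'
#' @param x input value (cumulative light, uE h).
#' @param u translational value, same units as `x`.
#' @param b positive half-saturation constant, same units as `x`.
#' @param clamp replace `x - u` by `max(x - u, 0)`.
#' @return Response in `[0, 1)` for clamped inputs.
#' @examples
#' monod(150, 50, 100)   # x - u == b -> 0.5
#' @export
monod <- function(x, u, b, clamp = TRUE) {
  if (!is.numeric(b) || any(b <= 0)) {
    stop("`b` must be a positive half constant", call. = FALSE)
  }
  d <- x - u
  if (clamp) {
    d <- pmax(d, 0)
  } else if (any(abs(b + d) < .Machine$double.eps * 4)) {
    stop("monod() singular: x - u == -b", call. = FALSE)
  }
  d / (b + d)
}
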