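## Conversion of grouped/aggregated inputs to single-year-of-age curves.
## Epidemiological support points are interpolated with natural cubic
## splines; grouped cost data are linearly interpolated between age-group
## midpoints. Both return a curve on integer ages 0-100.

#' Natural-spline interpolation of age-specific values
#'
#' Fits a natural cubic spline through `(age, value)` support points and
#' evaluates it at integer ages 0-100. Outside the outermost support points
#' the curve is extrapolated as a constant. With fewer than three points the
#' function falls back to linear interpolation with a warning. The result is
#' clipped to the payload's valid domain (proportions to [0, 1], rates and
#' costs to [0, Inf)).
#'
#' @param age numeric vector of support ages, strictly increasing.
#' @param value numeric vector of values at the support ages.
#' @param payload one of `"rate"`, `"proportion"`, `"cost"`; controls
#'   clipping of the interpolated curve.
#' @return numeric vector of length 101 named by age 0-100.
#' @examples
#' spline_ages(c(0, 50, 100), c(0.1, 0.1, 0.1), payload = "proportion")
#' @export
spline_ages <- function(age, value, payload = c("rate", "proportion", "cost")) {
  payload <- match.arg(payload)
  if (length(age) != length(value))
    stop("`age` and `value` must have equal length", call. = FALSE)
  if (anyDuplicated(age))
    stop("duplicate support ages", call. = FALSE)
  if (is.unsorted(age, strictly = TRUE))
    stop("support ages must be strictly increasing", call. = FALSE)
  stopifnot_finite(age, "support ages")
  stopifnot_finite(value, "support values")

  # constant extrapolation: clamp the query ages into the support range
  xout <- pmin(pmax(MODEL_AGES, min(age)), max(age))
  if (length(age) < 3L) {
    warning("fewer than 3 support points; falling back to linear interpolation",
            call. = FALSE)
    y <- stats::approx(age, value, xout = xout, rule = 2)$y
  } else {
    y <- stats::spline(age, value, xout = xout, method = "natural")$y
  }
  y <- clip_payload(y, payload)
  names(y) <- as.character(MODEL_AGES)
  y
}

#' Midpoint-anchored linear interpolation of age-group values
#'
#' Each age group `[lo, hi]` anchors its value at the midpoint
#' `(lo + hi) / 2`; the curve is piecewise linear between adjacent midpoints
#' and constant before the first and after the last midpoint. Groups must be
#' ordered and contiguous (no gaps or overlaps); ages outside the covered
#' range take the nearest midpoint's value.
#'
#' @param lo,hi integer group bounds (inclusive).
#' @param value numeric group values.
#' @param payload clipping domain, see [spline_ages()].
#' @return numeric vector of length 101 named by age 0-100.
#' @examples
#' linear_by_age_group(0, 100, 5)           # constant curve
#' linear_by_age_group(c(0, 5, 10), c(4, 9, 100), c(10, 20, 20))
#' @export
linear_by_age_group <- function(lo, hi, value,
                                payload = c("rate", "proportion", "cost")) {
  payload <- match.arg(payload)
  n <- length(lo)
  if (length(hi) != n || length(value) != n)
    stop("`lo`, `hi`, `value` must have equal length", call. = FALSE)
  if (n < 1L) stop("no age groups supplied", call. = FALSE)
  if (any(hi < lo)) stop("group with hi < lo", call. = FALSE)
  if (is.unsorted(lo, strictly = TRUE))
    stop("groups must be ordered by increasing lo", call. = FALSE)
  if (n > 1L && any(lo[-1L] != hi[-n] + 1L))
    stop("gaps or overlaps in age-group coverage", call. = FALSE)
  stopifnot_finite(value, "group values")

  mid <- (lo + hi) / 2
  if (n == 1L) {
    y <- rep(value, 101L)
  } else {
    y <- stats::approx(mid, value, xout = MODEL_AGES, rule = 2)$y
  }
  y <- clip_payload(y, payload)
  names(y) <- as.character(MODEL_AGES)
  y
}
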