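## Calendar-time trends on rate surfaces: proportional annual change applied
## multiplicatively from a reference year.

#' Apply a proportional annual trend to a base-year rate surface
#'
#' Expands a base-year age/sex surface over calendar years 2010-2040 with
#' `value(a, s, t) = value(a, s, ref) * (1 + trend)^(t - ref)`.
#'
#' @param base matrix `[age 0-100, sex]` of base-year values, or an array
#'   `[age, sex, year]` whose `reference_year` slice is used.
#' @param trend proportional change per calendar year (e.g. `0.01` for
#'   +1\%/year); must exceed -1.
#' @param reference_year calendar year of `base` (default 2010).
#' @return array `[age, sex, year 2010-2040]`.
#' @export
apply_trend <- function(base, trend, reference_year = 2010) {
  if (!is.numeric(trend) || length(trend) != 1L || trend <= -1)
    stop("trend must be a single number > -1", call. = FALSE)
  if (length(dim(base)) == 3L) {
    j <- match(as.character(reference_year), dimnames(base)$year)
    if (is.na(j)) stop("surface not defined at the reference year",
                       call. = FALSE)
    base <- base[, , j]
  }
  if (!is.matrix(base) || nrow(base) != 101L || ncol(base) != 2L)
    stop("base surface must be [age 0-100 x sex]", call. = FALSE)
  stopifnot_finite(base, "rate surface")
  out <- age_sex_year_array()
  mult <- (1 + trend)^(MODEL_YEARS - reference_year)
  for (j in seq_along(MODEL_YEARS)) out[, , j] <- base * mult[j]
  out
}

#' Apply a trend to a mortality-rate-ratio surface with a floor at 1
#'
#' As [apply_trend()], but wherever the base MRR is at least 1 a declining
#' trend is not allowed to push the ratio below 1, preventing a sign
#' inversion of excess mortality.
#'
#' @inheritParams apply_trend
#' @return array `[age, sex, year]`.
#' @export
apply_mrr_trend <- function(base, trend, reference_year = 2010) {
  out <- apply_trend(base, trend, reference_year)
  if (length(dim(base)) == 3L)
    base <- base[, , as.character(reference_year)]
  floor_mask <- base >= 1
  for (j in seq_len(dim(out)[3L]))
    out[, , j] <- ifelse(floor_mask, pmax(out[, , j], 1), out[, , j])
  out
}
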