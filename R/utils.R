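## Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so that seeded generators do
#' not perturb the global random stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Clip a curve to its payload's valid domain
#' @noRd
clip_payload <- function(x, payload = c("rate", "proportion", "cost")) {
  payload <- match.arg(payload)
  if (payload == "proportion") clip01(x) else pmax(x, 0)
}

stopifnot_finite <- function(x, what) {
  if (any(!is.finite(x)))
    stop(sprintf("non-finite values in %s", what), call. = FALSE)
}

#' Bilinear interpolation on an age x year matrix
#'
#' Rows index ages 0-100, columns years 2010-2040. Query points outside the
#' grid are clamped to the boundary (age 100 is an open-ended class; rates
#' are held constant beyond 2040 and before 2010).
#' @noRd
bilinear_at <- function(mat, age, year) {
  a <- pmin(pmax(age, 0), 100)
  t <- pmin(pmax(year - 2010, 0), 30)
  i0 <- pmin(floor(a), 99L); fa <- a - i0
  j0 <- pmin(floor(t), 29L); ft <- t - j0
  i0 <- as.integer(i0) + 1L
  j0 <- as.integer(j0) + 1L
  (1 - fa) * (1 - ft) * mat[cbind(i0, j0)] +
    fa     * (1 - ft) * mat[cbind(i0 + 1L, j0)] +
    (1 - fa) * ft     * mat[cbind(i0, j0 + 1L)] +
    fa     * ft       * mat[cbind(i0 + 1L, j0 + 1L)]
}

#' Check that two arrays share dimnames on the named dimensions
#' @noRd
check_common_grid <- function(a, b, what_a, what_b) {
  da <- dimnames(a); db <- dimnames(b)
  shared <- intersect(names(da), names(db))
  for (nm in shared) {
    if (!identical(da[[nm]], db[[nm]]))
      stop(sprintf("grid mismatch between %s and %s on dimension '%s'",
                   what_a, what_b, nm), call. = FALSE)
  }
  invisible(TRUE)
}

## dimnamed array constructors ------------------------------------------------

age_sex_array <- function(data = 0) {
  array(data, dim = c(101L, 2L),
        dimnames = list(age = as.character(MODEL_AGES), sex = MODEL_SEXES))
}

age_sex_year_array <- function(data = 0) {
  array(data, dim = c(101L, 2L, 31L),
        dimnames = list(age = as.character(MODEL_AGES), sex = MODEL_SEXES,
                        year = as.character(MODEL_YEARS)))
}

age_sex_type_array <- function(data = 0) {
  array(data, dim = c(101L, 2L, 2L),
        dimnames = list(age = as.character(MODEL_AGES), sex = MODEL_SEXES,
                        type = MODEL_TYPES))
}

age_sex_type_year_array <- function(data = 0) {
  array(data, dim = c(101L, 2L, 2L, 31L),
        dimnames = list(age = as.character(MODEL_AGES), sex = MODEL_SEXES,
                        type = MODEL_TYPES, year = as.character(MODEL_YEARS)))
}
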