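## Synthetic demographic inputs: a simplified cohort-component population
## generator standing in for the official (FSO-style) projection variants.
## The pipeline only consumes N(a, s, t); variants are parameterised by
## three knobs: birth rate (G), life expectancy at birth in 2040 (L) and
## annual net migration (W).

#' Demographic variant parameters
#'
#' Returns the parameter set of one of six named projection variants.
#' The baseline `G2L2W2` assumes a birth rate of 1.55 children per woman,
#' life expectancy at birth in 2040 of about 84 (men) and 88 (women) years
#' and a long-term net migration of 290,000 people per year. The other
#' variants perturb one knob at a time: `W1`/`W3` low/high migration,
#' `G1` lower birth rate, `L1`/`L3` slower/faster gains in life expectancy.
#'
#' @param variant_id one of `"G2L2W2"`, `"G2L2W1"`, `"G2L2W3"`, `"G1L2W2"`,
#'   `"G2L1W2"`, `"G2L3W2"`.
#' @return an object of class `demographic_variant`: a list with fields
#'   `variant_id`, `fertility` (children per woman), `life_expectancy_2040`
#'   (named numeric, years at birth per sex) and `net_migration`
#'   (persons per year).
#' @export
demographic_variant <- function(variant_id = "G2L2W2") {
  presets <- list(
    G2L2W2 = list(fertility = 1.55, le = c(male = 84, female = 88),
                  mig = 290000),
    G2L2W1 = list(fertility = 1.55, le = c(male = 84, female = 88),
                  mig = 100000),
    G2L2W3 = list(fertility = 1.55, le = c(male = 84, female = 88),
                  mig = 400000),
    G1L2W2 = list(fertility = 1.40, le = c(male = 84, female = 88),
                  mig = 290000),
    G2L1W2 = list(fertility = 1.55, le = c(male = 82, female = 86),
                  mig = 290000),
    G2L3W2 = list(fertility = 1.55, le = c(male = 86, female = 90),
                  mig = 290000)
  )
  if (!variant_id %in% names(presets))
    stop("unknown demographic variant: ", variant_id, call. = FALSE)
  p <- presets[[variant_id]]
  new_demographic_variant(variant_id, p$fertility, p$le, p$mig)
}

#' Construct and validate demographic variant parameters
#'
#' @param variant_id character label.
#' @param fertility children per woman, > 0.
#' @param life_expectancy_2040 named numeric `c(male = , female = )`, years
#'   at birth, each in (40, 110).
#' @param net_migration persons per year (may be negative).
#' @return object of class `demographic_variant`.
#' @export
new_demographic_variant <- function(variant_id, fertility,
                                    life_expectancy_2040, net_migration) {
  if (!is.numeric(fertility) || fertility <= 0)
    stop("fertility must be > 0", call. = FALSE)
  le <- life_expectancy_2040[MODEL_SEXES]
  if (any(is.na(le)) || any(le <= 40) || any(le >= 110))
    stop("life_expectancy_2040 must be given per sex, each in (40, 110)",
         call. = FALSE)
  if (!is.finite(net_migration))
    stop("net_migration must be finite", call. = FALSE)
  structure(list(variant_id = variant_id, fertility = fertility,
                 life_expectancy_2040 = le, net_migration = net_migration),
            class = "demographic_variant")
}

## Gompertz-Makeham mortality machinery ---------------------------------------

gm_hazard <- function(ages, makeham, level, slope) {
  makeham + level * exp(slope * ages)
}

# period life expectancy at birth from an age schedule of hazards; age 100
# is treated as an open-ended class with constant hazard m[101]
life_expectancy_from_rates <- function(m) {
  px <- exp(-m)
  lx <- c(1, cumprod(px))           # survivors at exact ages 0..101
  person_years <- (lx[1:101] + lx[2:102]) / 2
  tail <- lx[102] / max(m[101], 1e-8)
  sum(person_years) + tail
}

# scale factor k such that life expectancy of k * m equals target
calibrate_mortality_scale <- function(m, target_e0) {
  f <- function(k) life_expectancy_from_rates(k * m) - target_e0
  stats::uniroot(f, c(1e-4, 50), tol = 1e-10)$root
}

# default Gompertz-Makeham parameters per sex, slope fixed; levels tuned at
# call time so 2010 period life expectancy is about 77.5 (men) / 82.6 (women)
default_gm_params <- function() {
  list(makeham = 3e-4, slope = 0.095,
       e0_2010 = c(male = 77.5, female = 82.6))
}

#' General-population mortality surface for a demographic variant
#'
#' Builds an age/sex/year hazard surface from a Gompertz-Makeham schedule
#' whose overall level is tuned each calendar year (by scaling) so that
#' period life expectancy at birth moves linearly from its 2010 value to the
#' variant's 2040 target.
#'
#' @param params a `demographic_variant`.
#' @return array `[age 0-100, sex, year 2010-2040]` of hazards per
#'   person-year.
#' @export
mortality_surface <- function(params) {
  gm <- default_gm_params()
  m <- age_sex_year_array()
  for (s in MODEL_SEXES) {
    base <- gm_hazard(MODEL_AGES, gm$makeham, 1e-5, gm$slope)
    k0 <- calibrate_mortality_scale(base, gm$e0_2010[[s]])
    m2010 <- k0 * base
    e_targets <- seq(gm$e0_2010[[s]], params$life_expectancy_2040[[s]],
                     length.out = 31L)
    for (j in seq_along(MODEL_YEARS)) {
      kj <- calibrate_mortality_scale(m2010, e_targets[j])
      m[, s, j] <- kj * m2010
    }
  }
  m
}

## Base pyramid ---------------------------------------------------------------

#' Synthetic base-year population pyramid
#'
#' A smooth, German-like 2010 age structure: small birth cohorts, a bulge
#' around ages 40-50 and attrition beyond age 70, totalling about 81.8
#' million people. This is a synthetic stand-in, not official census data.
#'
#' @return matrix `[age 0-100, sex]` of person counts.
#' @export
default_base_counts <- function() {
  a <- MODEL_AGES
  shape <- 0.68 +
    0.42 * exp(-((a - 45) / 13)^2) +
    0.12 * exp(-((a - 70) / 9)^2)
  shape <- shape / (1 + exp((a - 81) / 5.5))   # old-age attrition
  male_share <- pmax(0.512 - 0.003 * pmax(a - 60, 0), 0.35)
  counts <- cbind(male = shape * male_share, female = shape * (1 - male_share))
  counts <- counts * 81.8e6 / sum(counts)
  rownames(counts) <- as.character(a)
  names(dimnames(counts)) <- c("age", "sex")
  counts
}

# fixed triangular net-migration age profile peaking at age 25
migration_profile <- function() {
  w <- pmax(0, 1 - abs(MODEL_AGES - 25) / 35)
  w / sum(w)
}

#' Cohort-component population projection
#'
#' Ages a base-year population forward one calendar year at a time under
#' survival probabilities from the variant's mortality surface, adds
#' fertility-driven births (female population aged 15-49 times the birth
#' rate spread over a 35-year fertile span, 51.2\% of newborns male) and a
#' fixed triangular net-migration age profile peaking at age 25. Age 100 is
#' an absorbing open-ended class. The generator is deterministic; `seed` is
#' accepted for interface symmetry with the other generators and recorded on
#' the result.
#'
#' @param params a `demographic_variant`.
#' @param base_counts matrix `[age 0-100, sex]` of base-year (2010) counts.
#' @param seed integer, recorded on the result.
#' @param mortality optional override: a scalar hazard or an array
#'   `[age, sex, year]`; by default [mortality_surface()] of `params`.
#' @return array `[age 0-100, sex, year 2010-2040]` of person counts, class
#'   `population_projection`, with the mortality surface attached as
#'   attribute `"mortality"`.
#' @export
generate_population <- function(params, base_counts = default_base_counts(),
                                seed = 2010, mortality = NULL) {
  if (!inherits(params, "demographic_variant"))
    stop("`params` must be a demographic_variant", call. = FALSE)
  if (!is.matrix(base_counts) || nrow(base_counts) != 101L ||
      ncol(base_counts) != 2L)
    stop("`base_counts` must cover ages 0-100 for both sexes", call. = FALSE)
  if (any(!is.finite(base_counts)) || any(base_counts < 0))
    stop("base counts must be finite and non-negative", call. = FALSE)

  if (is.null(mortality)) {
    m <- mortality_surface(params)
  } else if (length(mortality) == 1L) {
    m <- age_sex_year_array(mortality)
  } else {
    m <- mortality
    if (!identical(dim(m), c(101L, 2L, 31L)))
      stop("mortality override must be [101 x 2 x 31]", call. = FALSE)
  }
  if (any(!is.finite(m)) || any(m < 0))
    stop("mortality rates must be finite and non-negative", call. = FALSE)

  N <- age_sex_year_array()
  N[, , 1L] <- base_counts
  mig <- params$net_migration * migration_profile() / 2  # split by sex
  for (j in 1:30) {
    surv <- exp(-m[, , j])
    for (s in 1:2) {
      now <- N[, s, j]
      nxt <- numeric(101L)
      nxt[2:101] <- now[1:100] * surv[1:100, s]
      nxt[101L] <- nxt[101L] + now[101L] * surv[101L, s]  # absorbing class
      women <- sum(N[16:50, 2L, j])
      births <- params$fertility * women / 35
      nxt[1L] <- births * if (s == 1L) 0.512 else 0.488
      nxt <- pmax(nxt + mig, 0)
      N[, s, j + 1L] <- nxt
    }
  }
  structure(N, class = c("population_projection", class(N)),
            variant = params$variant_id, seed = seed, mortality = m)
}
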