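## Cost model: baseline per capita costs from the aggregated claims table,
## excess-cost projection under an annual growth rate, total and excess
## costs, cost ratios R, population attributable costs (PAC) and national
## extrapolation. Only the diabetes excess is subject to growth; per capita
## costs of people without diabetes are held at their 2010 level.

#' Baseline per capita cost profile from an aggregated cost table
#'
#' Per (diagnosis, sex, age group): per capita cost = sum of the six
#' expenditure-field costs divided by the member count (0, with a warning,
#' for empty strata). Group values are then carried to single ages 0-100 by
#' midpoint-anchored linear interpolation.
#'
#' @param table an `aggregated_cost_table` (or data.frame with the same
#'   columns).
#' @return object of class `percap_profile`: list with `c` (array
#'   `[age, sex, diagnosis]`, euro per person-year, base year 2010) and
#'   `excess` (array `[age, sex, type]`, `c_d - c_none`).
#' @export
baseline_per_capita <- function(table) {
  need <- c("field", "diagnosis", "sex", "age_lo", "age_hi",
            "total_cost_eur", "member_count")
  if (!all(need %in% names(table)))
    stop("cost table is missing required columns", call. = FALSE)
  if (any(table$total_cost_eur < 0) || any(table$member_count < 0))
    stop("negative entries in cost table", call. = FALSE)
  nexp <- length(EXPENDITURE_FIELDS) * length(MODEL_DIAGNOSES) *
    length(MODEL_SEXES) * nrow(cost_age_groups())
  if (nrow(table) != nexp)
    stop(sprintf("expected %d cost rows, got %d", nexp, nrow(table)),
         call. = FALSE)

  cprof <- array(0, dim = c(101L, 2L, 3L),
                 dimnames = list(age = as.character(MODEL_AGES),
                                 sex = MODEL_SEXES,
                                 diagnosis = MODEL_DIAGNOSES))
  n_empty <- 0L
  for (d in MODEL_DIAGNOSES) {
    for (s in MODEL_SEXES) {
      sub <- table[table$diagnosis == d & table$sex == s, ]
      agg <- stats::aggregate(total_cost_eur ~ age_lo + age_hi, data = sub,
                              FUN = sum)
      agg <- agg[order(agg$age_lo), ]
      members <- sub$member_count[match(agg$age_lo, sub$age_lo)]
      percap <- ifelse(members > 0, agg$total_cost_eur / members, 0)
      n_empty <- n_empty + sum(members == 0)
      cprof[, s, d] <- linear_by_age_group(agg$age_lo, agg$age_hi, percap,
                                           payload = "cost")
    }
  }
  if (n_empty > 0)
    warning(sprintf("%d strata with zero members; per capita set to 0",
                    n_empty), call. = FALSE)
  excess <- age_sex_type_array()
  for (d in MODEL_TYPES) excess[, , d] <- cprof[, , d] - cprof[, , "none"]
  structure(list(c = cprof, excess = excess, base_year = 2010),
            class = "percap_profile")
}

#' All-ages per capita cost aggregates of a cost table
#'
#' Total cost over all fields and age groups divided by total members, per
#' diagnosis and sex. Used to check the calibration of synthetic tables
#' against published 2010 headline values.
#'
#' @inheritParams baseline_per_capita
#' @return matrix `[diagnosis, sex]` in euro per person-year.
#' @export
aggregate_per_capita <- function(table) {
  out <- matrix(NA_real_, 3L, 2L,
                dimnames = list(diagnosis = MODEL_DIAGNOSES,
                                sex = MODEL_SEXES))
  for (d in MODEL_DIAGNOSES) for (s in MODEL_SEXES) {
    sub <- table[table$diagnosis == d & table$sex == s, ]
    members <- sum(sub$member_count) / length(EXPENDITURE_FIELDS)
    out[d, s] <- sum(sub$total_cost_eur) / members
  }
  out
}

#' Project per capita costs under excess-cost growth
#'
#' `c_d(a, s, t) = c_none(a, s) + e_d(a, s) * (1 + r)^(t - 2010)`; the per
#' capita costs of people without diabetes stay at their 2010 level.
#'
#' @param profile a `percap_profile`.
#' @param growth mean annual growth rate `r` of the excess costs (> -1).
#' @param years calendar years to evaluate (default 2010-2040).
#' @return array `[age, sex, diagnosis, year]` in euro per person-year.
#' @export
project_per_capita <- function(profile, growth, years = MODEL_YEARS) {
  if (!inherits(profile, "percap_profile"))
    stop("`profile` must be a percap_profile", call. = FALSE)
  if (growth <= -1) stop("growth rate must exceed -1", call. = FALSE)
  if (any(years < profile$base_year))
    stop("years must not precede the base year", call. = FALSE)
  out <- array(0, dim = c(101L, 2L, 3L, length(years)),
               dimnames = list(age = as.character(MODEL_AGES),
                               sex = MODEL_SEXES,
                               diagnosis = MODEL_DIAGNOSES,
                               year = as.character(years)))
  mult <- (1 + growth)^(years - profile$base_year)
  for (j in seq_along(years)) {
    out[, , "none", j] <- profile$c[, , "none"]
    for (d in MODEL_TYPES)
      out[, , d, j] <- profile$c[, , "none"] + profile$excess[, , d] * mult[j]
  }
  out
}

#' Total annual costs by diagnosis group
#'
#' `total_d(t) = sum_{a,s} N(a,s,t) * p_d(a,s,t) * c_d(a,s,t)`; the group
#' without diabetes uses `1 - p_T1 - p_T2` and `c_none`.
#'
#' @param prev prevalence `[age, sex, type, year]`.
#' @param pop population `[age, sex, year]`.
#' @param percap projected per capita costs `[age, sex, diagnosis, year]`.
#' @return array `[diagnosis, sex, year]` in euro.
#' @export
total_costs <- function(prev, pop, percap) {
  check_common_grid(prev, pop, "prevalence", "population")
  check_common_grid(percap, pop, "per capita costs", "population")
  years <- dimnames(pop)$year
  out <- array(0, dim = c(3L, 2L, length(years)),
               dimnames = list(diagnosis = MODEL_DIAGNOSES, sex = MODEL_SEXES,
                               year = years))
  pnone <- pmax(1 - prev[, , "T1", ] - prev[, , "T2", ], 0)
  for (s in seq_along(MODEL_SEXES)) {
    for (j in seq_along(years)) {
      for (d in MODEL_TYPES)
        out[d, s, j] <- sum(pop[, s, j] * prev[, s, d, j] * percap[, s, d, j])
      out["none", s, j] <- sum(pop[, s, j] * pnone[, s, j] *
                                 percap[, s, "none", j])
    }
  }
  out
}

#' Total annual excess costs
#'
#' As [total_costs()] but with per capita excess costs
#' `e_d(a, s) * (1 + r)^(t - 2010)` in place of full per capita costs.
#'
#' @inheritParams total_costs
#' @param profile a `percap_profile` supplying the base-year excess.
#' @param growth annual excess-cost growth rate.
#' @return array `[type, sex, year]` in euro.
#' @export
total_excess_costs <- function(prev, pop, profile, growth) {
  check_common_grid(prev, pop, "prevalence", "population")
  years <- as.integer(dimnames(pop)$year)
  mult <- (1 + growth)^(years - profile$base_year)
  out <- array(0, dim = c(2L, 2L, length(years)),
               dimnames = list(type = MODEL_TYPES, sex = MODEL_SEXES,
                               year = as.character(years)))
  for (d in MODEL_TYPES) for (s in seq_along(MODEL_SEXES))
    for (j in seq_along(years))
      out[d, s, j] <- sum(pop[, s, j] * prev[, s, d, j] *
                            profile$excess[, s, d] * mult[j])
  out
}

#' Age- and sex-specific cost ratios R
#'
#' `R(a, s, d, t) = c_d(a, s, t) / c_none(a, s)`, with a floor of one euro
#' on the denominator to keep sparse ages finite.
#'
#' @param percap projected per capita costs `[age, sex, diagnosis, year]`.
#' @return array `[age, sex, type, year]` of dimensionless ratios.
#' @export
cost_ratio <- function(percap) {
  denom <- pmax(percap[, , "none", ], 1)
  if (any(!is.finite(denom)) || any(denom <= 0))
    stop("invalid per capita costs of the non-diseased group", call. = FALSE)
  years <- dimnames(percap)$year
  out <- array(NA_real_, dim = c(101L, 2L, 2L, length(years)),
               dimnames = list(age = as.character(MODEL_AGES),
                               sex = MODEL_SEXES, type = MODEL_TYPES,
                               year = years))
  for (d in MODEL_TYPES) out[, , d, ] <- percap[, , d, ] / denom
  out
}

#' Population attributable costs
#'
#' `PAC = p * (R - 1) / (1 + p * (R - 1))`, clipped at 0 where `R < 1`
#' (protective strata), so values lie in [0, 1).
#'
#' @param prev prevalence `[age, sex, type, year]` in [0, 1].
#' @param ratio cost ratios `[age, sex, type, year]`, positive.
#' @return array `[age, sex, type, year]` of proportions.
#' @export
compute_pac <- function(prev, ratio) {
  check_common_grid(prev, ratio, "prevalence", "cost ratio")
  if (any(prev < 0 | prev > 1)) stop("prevalence outside [0, 1]",
                                     call. = FALSE)
  if (any(ratio <= 0)) stop("cost ratios must be positive", call. = FALSE)
  x <- prev * (ratio - 1)
  pmax(x / (1 + x), 0)
}

#' Stratum-level total costs for PAC aggregation
#'
#' Whole-population cost per (age, sex, year) stratum counting only the
#' excess of one diabetes type:
#' `N * (p_d * c_d + (1 - p_d) * c_none)`.
#'
#' @inheritParams total_costs
#' @return array `[age, sex, type, year]` in euro.
#' @export
stratum_total_costs <- function(prev, pop, percap) {
  check_common_grid(prev, pop, "prevalence", "population")
  out <- age_sex_type_year_array()
  for (d in MODEL_TYPES)
    out[, , d, ] <- pop * (prev[, , d, ] * percap[, , d, ] +
                             (1 - prev[, , d, ]) * percap[, , "none", ])
  out
}

#' Cost-weighted aggregate attributable fraction
#'
#' Aggregates the age/sex-specific PAC surface to one fraction per type and
#' year by cost weighting: sum of stratum attributable costs
#' (`stratum total * PAC`) over total stratum costs. By the PAC identity
#' this equals total excess costs over whole-population costs counting only
#' that type's excess.
#'
#' @param pac PAC surface `[age, sex, type, year]`.
#' @param totals stratum totals `[age, sex, type, year]`, see
#'   [stratum_total_costs()].
#' @return matrix `[type, year]` of proportions.
#' @export
aggregate_pac <- function(pac, totals) {
  check_common_grid(pac, totals, "PAC", "stratum totals")
  years <- dimnames(pac)$year
  out <- matrix(NA_real_, 2L, length(years),
                dimnames = list(type = MODEL_TYPES, year = years))
  for (d in MODEL_TYPES) for (j in seq_along(years)) {
    tot <- sum(totals[, , d, j])
    if (tot <= 0) stop("zero total cost in year ", years[j], call. = FALSE)
    out[d, j] <- sum(totals[, , d, j] * pac[, , d, j]) / tot
  }
  out
}

#' National extrapolation of attributable costs
#'
#' The claims sample covers a fraction of the insured population; dividing
#' the sample's total costs by the sampling fraction yields the national
#' total, and multiplying by the aggregate attributable fraction gives the
#' national attributable euro amount.
#'
#' @param aggregate_pac attributable fraction(s), in [0, 1).
#' @param sample_total_cost total cost(s) observed in the sample, euro.
#' @param sample_fraction sampling fraction in (0, 1].
#' @return list with `national_total` and `attributable` (euro), vectorised
#'   over years.
#' @export
extrapolate_national <- function(aggregate_pac, sample_total_cost,
                                 sample_fraction) {
  if (length(sample_fraction) != 1L || sample_fraction <= 0 ||
      sample_fraction > 1)
    stop("sample_fraction must be in (0, 1]", call. = FALSE)
  national <- sample_total_cost / sample_fraction
  list(national_total = national, attributable = national * aggregate_pac)
}
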