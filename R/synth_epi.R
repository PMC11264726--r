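## Synthetic epidemiological inputs: age/sex/type prevalence in the base
## year, incidence, general mortality and mortality rate ratios (MRR).
## Shapes follow the clinical picture of the two diabetes types: type 1
## prevalence rises through childhood to a plateau, type 2 rises
## logistically with age; MRRs decline with age. Prevalence shapes are
## rescaled so that the population-weighted 2010 prevalence hits the
## configured targets (defaults: 7% for type 2, 0.3% for type 1).

#' Default configuration of the epidemiological generator
#'
#' @param target_prevalence named numeric: population-weighted base-year
#'   prevalence targets per type.
#' @param noise_sd standard deviation of multiplicative log-normal jitter
#'   applied per age to prevalence and incidence (0 disables it).
#' @return list of shape functions and parameters consumed by
#'   [generate_epi_inputs()].
#' @export
epi_config <- function(target_prevalence = c(T1 = 0.003, T2 = 0.07),
                       noise_sd = 0.01) {
  list(
    target_prevalence = target_prevalence,
    noise_sd = noise_sd,
    # unit-scale prevalence shapes; rescaled against the reference population
    prev_shape = list(
      T1 = function(a) 1 - exp(-(a / 12)^1.6),
      T2 = function(a) 1 / (1 + exp(-(a - 66) / 9.5))
    ),
    # male/female multiplier applied before rescaling
    sex_factor = list(T1 = c(male = 1.05, female = 0.95),
                      T2 = c(male = 1.06, female = 0.94)),
    incidence_shape = list(
      T1 = function(a) 3e-4 * exp(-((a - 12) / 16)^2) + 2e-5,
      T2 = function(a) 0.016 / (1 + exp(-(a - 62) / 11))
    ),
    mrr_shape = list(
      T1 = function(a) 1 + 6.0 * exp(-pmax(a - 20, 0) / 35),
      T2 = function(a) 1 + 2.6 * exp(-pmax(a - 40, 0) / 30)
    )
  )
}

#' Generate synthetic epidemiological inputs
#'
#' Evaluates the configured age shapes on the model grid, rescales the
#' prevalence shapes so that the population-weighted base-year (2010)
#' prevalence equals the configured targets against the supplied population,
#' and applies seeded multiplicative jitter to prevalence and incidence.
#'
#' @param config see [epi_config()].
#' @param pop a `population_projection`; its 2010 cross-section provides the
#'   weights and its attached mortality surface the general mortality.
#' @param seed integer RNG seed.
#' @return object of class `epi_inputs`: list with `prevalence0`
#'   `[age, sex, type]` (proportions), `incidence` `[age, sex, type]`
#'   (rates per person-year), `mortality_general` `[age, sex]` (2010 rates)
#'   and `mrr` `[age, sex, type]` (dimensionless ratios).
#' @export
generate_epi_inputs <- function(config = epi_config(),
                                pop = NULL, seed = 2010) {
  if (is.null(pop))
    pop <- generate_population(demographic_variant("G2L2W2"))
  N0 <- pop[, , "2010"]
  w <- N0 / sum(N0)

  prev <- age_sex_type_array()
  inc <- age_sex_type_array()
  mrr <- age_sex_type_array()
  for (d in MODEL_TYPES) {
    shape <- config$prev_shape[[d]](MODEL_AGES)
    for (s in MODEL_SEXES) {
      prev[, s, d] <- shape * config$sex_factor[[d]][[s]]
      inc[, s, d] <- config$incidence_shape[[d]](MODEL_AGES)
      mrr[, s, d] <- config$mrr_shape[[d]](MODEL_AGES)
    }
    # rescale to hit the weighted target exactly (pre-noise)
    weighted <- sum(w * prev[, , d])
    if (weighted <= 0) stop("degenerate prevalence shape for ", d,
                            call. = FALSE)
    prev[, , d] <- prev[, , d] * config$target_prevalence[[d]] / weighted
  }

  if (config$noise_sd > 0) {
    with_seed(seed, {
      prev <- prev * exp(stats::rnorm(length(prev), 0, config$noise_sd))
      inc <- inc * exp(stats::rnorm(length(inc), 0, config$noise_sd))
    })
  }

  if (any(prev > 1))
    stop("configured shapes produce prevalence > 1", call. = FALSE)
  if (any(prev < 0) || any(inc < 0) || any(mrr < 0))
    stop("negative epidemiological rates", call. = FALSE)

  mort <- attr(pop, "mortality")
  mortality_general <- if (is.null(mort)) {
    mortality_surface(demographic_variant("G2L2W2"))[, , "2010"]
  } else mort[, , "2010"]

  structure(list(prevalence0 = prev, incidence = inc,
                 mortality_general = mortality_general, mrr = mrr,
                 seed = seed),
            class = "epi_inputs")
}
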