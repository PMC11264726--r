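## Scenario machinery: 16 deterministic futures varying epidemiological
## trends (scenarios 1-8), excess-cost growth (9, 10) and demographic
## variants (11-15); scenario 16 combines moderate trends and is treated as
## the most probable. Scenarios 2-5 and 11-15 are configurable defaults;
## 1, 6, 7, 8, 9, 10 and 16 are pinned.

new_scenario_spec <- function(id, label, variant, incidence_trend, mrr_trend,
                              cost_growth, constant_prevalence = FALSE) {
  if (constant_prevalence && (incidence_trend != 0 || mrr_trend != 0))
    stop("a constant-prevalence scenario cannot carry epidemiological trends",
         call. = FALSE)
  structure(list(id = as.integer(id), label = label, variant = variant,
                 incidence_trend = incidence_trend, mrr_trend = mrr_trend,
                 cost_growth = cost_growth,
                 constant_prevalence = isTRUE(constant_prevalence)),
            class = "scenario_spec")
}

#' Build the scenario table
#'
#' Returns the 16 scenario specifications. Pinned scenarios: 1 (base case:
#' baseline demographics, MRR -2\%/year, no other trend), 6/7 (incidence
#' +/-5\%/year), 8 (age- and sex-specific prevalence held constant at 2010),
#' 9/10 (excess-cost growth 1\% / 5\% per year) and 16 (most probable:
#' incidence +1\%/year, MRR -2\%/year, cost growth 1\%/year). Scenarios 2-5
#' (incidence +/-1\%, +/-2\%) and 11-15 (demographic variants) are
#' documented defaults that can be overridden via `config`.
#'
#' @param config optional named list of overrides, keyed `"s<id>"`, each a
#'   list of fields to replace (e.g.
#'   `list(s2 = list(incidence_trend = 0.015))`).
#' @return list of 16 `scenario_spec` objects, ids 1-16.
#' @export
build_scenarios <- function(config = NULL) {
  base <- list(
    list(1, "base case: MRR -2%/yr", "G2L2W2", 0, -0.02, 0, FALSE),
    list(2, "incidence +1%/yr", "G2L2W2", 0.01, -0.02, 0, FALSE),
    list(3, "incidence -1%/yr", "G2L2W2", -0.01, -0.02, 0, FALSE),
    list(4, "incidence +2%/yr", "G2L2W2", 0.02, -0.02, 0, FALSE),
    list(5, "incidence -2%/yr", "G2L2W2", -0.02, -0.02, 0, FALSE),
    list(6, "incidence +5%/yr", "G2L2W2", 0.05, -0.02, 0, FALSE),
    list(7, "incidence -5%/yr", "G2L2W2", -0.05, -0.02, 0, FALSE),
    list(8, "constant prevalence at 2010", "G2L2W2", 0, 0, 0, TRUE),
    list(9, "cost growth 1%/yr", "G2L2W2", 0, -0.02, 0.01, FALSE),
    list(10, "cost growth 5%/yr", "G2L2W2", 0, -0.02, 0.05, FALSE),
    list(11, "low migration", "G2L2W1", 0, -0.02, 0, FALSE),
    list(12, "high migration", "G2L2W3", 0, -0.02, 0, FALSE),
    list(13, "low birth rate", "G1L2W2", 0, -0.02, 0, FALSE),
    list(14, "slower ageing (lower life expectancy)", "G2L1W2", 0, -0.02, 0,
         FALSE),
    list(15, "stronger ageing (higher life expectancy)", "G2L3W2", 0, -0.02,
         0, FALSE),
    list(16, "most probable: incidence +1%, MRR -2%, cost growth 1%",
         "G2L2W2", 0.01, -0.02, 0.01, FALSE)
  )
  specs <- lapply(base, function(x) do.call(new_scenario_spec, x))
  if (!is.null(config)) {
    for (key in names(config)) {
      id <- as.integer(sub("^s", "", key))
      if (is.na(id) || id < 1L || id > 16L)
        stop("scenario override key must be s1..s16: ", key, call. = FALSE)
      spec <- specs[[id]]
      for (f in names(config[[key]])) spec[[f]] <- config[[key]][[f]]
      specs[[id]] <- do.call(new_scenario_spec, spec[c(
        "id", "label", "variant", "incidence_trend", "mrr_trend",
        "cost_growth", "constant_prevalence")])
    }
  }
  ids <- vapply(specs, `[[`, integer(1), "id")
  if (anyDuplicated(ids)) stop("duplicate scenario ids", call. = FALSE)
  names(specs) <- paste0("s", ids)
  specs
}

#' Prepare the shared inputs of a scenario run
#'
#' Generates (or accepts) the populations for every demographic variant the
#' scenario set needs, the epidemiological inputs and the aggregated cost
#' table, all from one seed.
#'
#' @param scenarios list of `scenario_spec`s (default [build_scenarios()]).
#' @param seed integer seed for all generators.
#' @param epi_cfg,cost_cfg generator configurations.
#' @return list with `populations` (named by variant), `epi`, `cost_table`,
#'   `sample_fraction`.
#' @export
prepare_inputs <- function(scenarios = build_scenarios(), seed = 2010,
                           epi_cfg = epi_config(), cost_cfg = cost_config()) {
  variants <- unique(vapply(scenarios, `[[`, character(1), "variant"))
  pops <- lapply(variants, function(v)
    generate_population(demographic_variant(v), seed = seed))
  names(pops) <- variants
  baseline <- if ("G2L2W2" %in% variants) pops[["G2L2W2"]] else pops[[1L]]
  epi <- generate_epi_inputs(epi_cfg, pop = baseline, seed = seed)
  tab <- generate_cost_table(cost_cfg, epi, baseline, seed = seed)
  profile <- suppressWarnings(baseline_per_capita(tab))
  list(populations = pops, epi = epi, cost_table = tab, profile = profile,
       sample_fraction = attr(tab, "sample_fraction"))
}

#' Run one scenario through the full pipeline
#'
#' Order: apply trends to incidence and MRR, integrate the IDM PDE (or hold
#' the 2010 prevalence cross-section constant for constant-prevalence
#' scenarios), convert to case counts, project per capita costs, and derive
#' totals, excess costs, cost ratios, PAC and the national extrapolation.
#'
#' @param spec a `scenario_spec`.
#' @param inputs output of [prepare_inputs()].
#' @param step PDE integration step in years.
#' @return object of class `projection_result`: list with elements
#'   `scenario`, `prevalence`, `counts`, `count_totals`, `per_capita`
#'   (aggregate euro per person with the condition, `[type, year]`),
#'   `totals` (`[diagnosis, sex, year]`), `excess` (`[type, sex, year]`),
#'   `ratio`, `pac` (age-resolved surfaces), `aggregate_pac`
#'   (`[type, year]`) and `attributable` (`[type, year]`, euro).
#' @export
run_scenario <- function(spec, inputs, step = 0.25) {
  if (!inherits(spec, "scenario_spec"))
    stop("`spec` must be a scenario_spec", call. = FALSE)
  pop <- inputs$populations[[spec$variant]]
  if (is.null(pop))
    stop("no population generated for variant ", spec$variant, call. = FALSE)
  epi <- inputs$epi
  mort_surface <- attr(pop, "mortality")

  if (spec$constant_prevalence) {
    prev <- age_sex_type_year_array()
    for (j in seq_along(MODEL_YEARS)) prev[, , , j] <- epi$prevalence0
  } else {
    inc <- array(NA_real_, dim = c(101L, 2L, 2L, 31L),
                 dimnames = dimnames(age_sex_type_year_array()))
    rr <- inc
    for (d in MODEL_TYPES) {
      inc[, , d, ] <- apply_trend(epi$incidence[, , d], spec$incidence_trend)
      rr[, , d, ] <- apply_mrr_trend(epi$mrr[, , d], spec$mrr_trend)
    }
    prev <- solve_idm_pde(epi$prevalence0, inc, mort_surface, rr, step = step)
  }

  cc <- case_counts(prev, pop)
  profile <- inputs$profile
  if (is.null(profile)) profile <- baseline_per_capita(inputs$cost_table)
  percap <- project_per_capita(profile, spec$cost_growth)
  totals <- total_costs(prev, pop, percap)
  excess <- total_excess_costs(prev, pop, profile, spec$cost_growth)
  ratio <- cost_ratio(percap)
  pac <- compute_pac(prev, ratio)
  strat <- stratum_total_costs(prev, pop, percap)
  agg_pac <- aggregate_pac(pac, strat)

  # whole-population total cost (both types priced at their own per capita)
  pop_total <- apply(totals, 3L, sum)
  sample_total <- inputs$sample_fraction * pop_total
  extrap <- extrapolate_national(agg_pac,
                                 matrix(sample_total, nrow = 2L, ncol = 31L,
                                        byrow = TRUE,
                                        dimnames = dimnames(agg_pac)),
                                 inputs$sample_fraction)

  # aggregate per capita cost among people with each type
  per_capita <- matrix(NA_real_, 2L, 31L, dimnames =
                         list(type = MODEL_TYPES,
                              year = as.character(MODEL_YEARS)))
  for (d in MODEL_TYPES) {
    cases <- apply(cc$counts[, , d, ], 3L, sum)
    per_capita[d, ] <- apply(totals[d, , , drop = FALSE], 3L, sum) / cases
  }

  structure(list(scenario = spec, prevalence = prev, counts = cc$counts,
                 count_totals = cc$totals, per_capita = per_capita,
                 totals = totals, excess = excess, ratio = ratio, pac = pac,
                 aggregate_pac = agg_pac,
                 attributable = extrap$attributable),
            class = "projection_result")
}

#' Percent change of total annual costs between two years
#'
#' @param result a `projection_result`.
#' @param from_year,to_year calendar years (default 2010 and 2040).
#' @return named numeric: percent change per diabetes type,
#'   `100 * (total(to) - total(from)) / total(from)` with totals summed over
#'   sexes.
#' @export
percent_change <- function(result, from_year = 2010, to_year = 2040) {
  tot <- result$totals
  yrs <- dimnames(tot)$year
  if (!all(as.character(c(from_year, to_year)) %in% yrs))
    stop("requested years not present in the result", call. = FALSE)
  out <- vapply(MODEL_TYPES, function(d) {
    a <- sum(tot[d, , as.character(from_year)])
    b <- sum(tot[d, , as.character(to_year)])
    if (a == 0) stop("zero baseline total for ", d, call. = FALSE)
    100 * (b - a) / a
  }, numeric(1))
  out
}
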