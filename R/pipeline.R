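## End-to-end pipeline: CSV interchange schemas, configuration handling and
## the run driver behind the command-line interface. CSV is the interchange
## format throughout; euro amounts are written with 2 decimals, proportions
## with 6.

## CSV writers/readers --------------------------------------------------------

#' Write and read the pipeline's CSV schemas
#'
#' Population: `age, sex, year, count`. Epidemiological inputs:
#' `age, sex, type, prevalence, incidence, mortality, mrr` (general
#' mortality duplicated across types). Cost table: `field, diagnosis, sex,
#' age_lo, age_hi, total_cost_eur, member_count`.
#'
#' @param pop,epi,table,path objects and file path.
#' @return readers return the corresponding in-memory objects.
#' @name pipeline-io
NULL

#' @rdname pipeline-io
#' @export
write_population_csv <- function(pop, path) {
  df <- as.data.frame.table(unclass(pop), responseName = "count",
                            stringsAsFactors = FALSE)
  df$age <- as.integer(df$age); df$year <- as.integer(df$year)
  df$count <- round(df$count, 3)
  utils::write.csv(df[order(df$year, df$sex, df$age), ], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname pipeline-io
#' @export
read_population_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  pop <- age_sex_year_array()
  pop[cbind(df$age + 1L, match(df$sex, MODEL_SEXES),
            df$year - 2009L)] <- df$count
  structure(pop, class = c("population_projection", class(pop)))
}

#' @rdname pipeline-io
#' @export
write_epi_csv <- function(epi, path) {
  grid <- expand.grid(age = MODEL_AGES, sex = MODEL_SEXES, type = MODEL_TYPES,
                      stringsAsFactors = FALSE)
  idx3 <- cbind(grid$age + 1L, match(grid$sex, MODEL_SEXES),
                match(grid$type, MODEL_TYPES))
  idx2 <- idx3[, 1:2]
  df <- data.frame(grid,
                   prevalence = round(epi$prevalence0[idx3], 6),
                   incidence = signif(epi$incidence[idx3], 7),
                   mortality = signif(epi$mortality_general[idx2], 7),
                   mrr = round(epi$mrr[idx3], 6))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname pipeline-io
#' @export
read_epi_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  prev <- age_sex_type_array(); inc <- age_sex_type_array()
  mrr <- age_sex_type_array(); mort <- age_sex_array()
  idx3 <- cbind(df$age + 1L, match(df$sex, MODEL_SEXES),
                match(df$type, MODEL_TYPES))
  prev[idx3] <- df$prevalence
  inc[idx3] <- df$incidence
  mrr[idx3] <- df$mrr
  mort[idx3[, 1:2]] <- df$mortality
  structure(list(prevalence0 = prev, incidence = inc,
                 mortality_general = mort, mrr = mrr, seed = NA_integer_),
            class = "epi_inputs")
}

#' @rdname pipeline-io
#' @export
write_cost_table_csv <- function(table, path) {
  df <- as.data.frame(table)
  df$total_cost_eur <- round(df$total_cost_eur, 2)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname pipeline-io
#' @param sample_fraction sampling fraction to attach when reading.
#' @export
read_cost_table_csv <- function(path, sample_fraction = 0.068) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(df, class = c("aggregated_cost_table", "data.frame"),
            sample_fraction = sample_fraction)
}

## Configuration --------------------------------------------------------------

#' Default run configuration
#'
#' @param out output directory.
#' @param seed integer seed for the synthetic generators.
#' @param variant baseline demographic variant label.
#' @param scenarios integer scenario ids to run (subset of 1-16).
#' @param step PDE integration step in years.
#' @param sample_fraction claims sampling fraction.
#' @param inputs optional named list of CSV paths (`population`, `epi`,
#'   `cost_table`); when given, these are read instead of synthesising.
#' @return list of class `run_config`.
#' @export
run_config <- function(out = "chronicost-out", seed = 2010,
                       variant = "G2L2W2", scenarios = c(1, 6:10, 16),
                       step = 0.25, sample_fraction = 0.068,
                       inputs = NULL) {
  cfg <- list(out = out, seed = as.integer(seed), variant = variant,
              scenarios = as.integer(scenarios), step = step,
              sample_fraction = sample_fraction, inputs = inputs)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  if (!all(cfg$scenarios %in% 1:16))
    stop("scenario ids must lie in 1..16", call. = FALSE)
  if (cfg$step <= 0 || cfg$step > 1) stop("step must be in (0, 1]",
                                          call. = FALSE)
  if (cfg$sample_fraction <= 0 || cfg$sample_fraction > 1)
    stop("sample_fraction must be in (0, 1]", call. = FALSE)
  if (!is.null(cfg$inputs)) {
    missing <- !vapply(unlist(cfg$inputs), file.exists, logical(1))
    if (any(missing))
      stop("missing input file(s): ",
           paste(unlist(cfg$inputs)[missing], collapse = ", "),
           call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a JSON file
#' @param path JSON file with the fields of [run_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw)
}

## Pipeline driver ------------------------------------------------------------

format_results_df <- function(result) {
  spec <- result$scenario
  grid <- expand.grid(year = MODEL_YEARS, sex = MODEL_SEXES,
                      type = MODEL_TYPES, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    y <- as.character(grid$year[k]); s <- grid$sex[k]; d <- grid$type[k]
    cases <- sum(result$counts[, s, d, y])
    data.frame(
      scenario_id = spec$id, year = grid$year[k], sex = s, type = d,
      total_cost_eur = round(result$totals[d, s, y], 2),
      total_excess_eur = round(result$excess[d, s, y], 2),
      per_capita_eur = round(if (cases > 0)
        result$totals[d, s, y] / cases else NA_real_, 2),
      aggregate_pac = round(result$aggregate_pac[d, y], 6),
      attributable_eur = round(result$attributable[d, y], 2))
  })
  do.call(rbind, rows)
}

#' Run the full projection pipeline
#'
#' Synthesises (or reads) all inputs, runs the selected scenarios and writes
#' per-scenario result CSVs, a cross-scenario summary table and a
#' machine-readable JSON run log. Reruns with the same configuration
#' produce identical files.
#'
#' @param config a `run_config`.
#' @return invisibly, the list of `projection_result`s (named `s<id>`).
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(unclass(config))
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)

  specs <- build_scenarios()[paste0("s", config$scenarios)]
  if (!is.null(config$inputs)) {
    pop <- read_population_csv(config$inputs$population)
    attr(pop, "mortality") <-
      mortality_surface(demographic_variant(config$variant))
    epi <- read_epi_csv(config$inputs$epi)
    tab <- read_cost_table_csv(config$inputs$cost_table,
                               config$sample_fraction)
    pops <- list(pop)
    names(pops) <- config$variant
    # non-baseline variants still come from the generator
    for (v in setdiff(unique(vapply(specs, `[[`, character(1), "variant")),
                      config$variant))
      pops[[v]] <- generate_population(demographic_variant(v),
                                       seed = config$seed)
    inputs <- list(populations = pops, epi = epi, cost_table = tab,
                   profile = suppressWarnings(baseline_per_capita(tab)),
                   sample_fraction = config$sample_fraction)
  } else {
    inputs <- prepare_inputs(specs, seed = config$seed,
                             cost_cfg = cost_config(
                               sample_fraction = config$sample_fraction))
  }

  results <- lapply(specs, run_scenario, inputs = inputs, step = config$step)
  summary_rows <- list()
  for (res in results) {
    df <- format_results_df(res)
    utils::write.csv(df, file.path(config$out,
                                   sprintf("scenario_%02d.csv",
                                           res$scenario$id)),
                     row.names = FALSE, quote = FALSE)
    pc <- percent_change(res)
    for (d in MODEL_TYPES) {
      summary_rows[[length(summary_rows) + 1L]] <- data.frame(
        scenario_id = res$scenario$id, type = d,
        total_2010_eur = round(sum(res$totals[d, , "2010"]), 2),
        total_2040_eur = round(sum(res$totals[d, , "2040"]), 2),
        percent_change = round(pc[[d]], 2),
        per_capita_2040_eur = round(res$per_capita[d, "2040"], 2),
        aggregate_pac_2040 = round(res$aggregate_pac[d, "2040"], 6))
    }
  }
  utils::write.csv(do.call(rbind, summary_rows),
                   file.path(config$out, "summary.csv"),
                   row.names = FALSE, quote = FALSE)

  log <- list(seed = config$seed, scenarios = config$scenarios,
              step = config$step, sample_fraction = config$sample_fraction,
              variant = config$variant,
              package_version = as.character(utils::packageVersion("chronicost")),
              r_version = paste(R.version$major, R.version$minor, sep = "."),
              input_md5 = if (!is.null(config$inputs))
                as.list(tools::md5sum(unlist(config$inputs))) else NULL)
  jsonlite::write_json(log, file.path(config$out, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(results)
}

#' Write synthetic input fixtures to a directory
#'
#' Generates the population, epidemiological and cost-table CSVs for one
#' demographic variant and seed.
#'
#' @param out output directory.
#' @param variant demographic variant label.
#' @param seed integer seed.
#' @return invisibly, the paths written.
#' @export
synthesize_inputs <- function(out, variant = "G2L2W2", seed = 2010) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  pop <- generate_population(demographic_variant(variant), seed = seed)
  epi <- generate_epi_inputs(pop = pop, seed = seed)
  tab <- generate_cost_table(cost_config(), epi, pop, seed = seed)
  paths <- c(population = file.path(out, "population.csv"),
             epi = file.path(out, "epi.csv"),
             cost_table = file.path(out, "cost_table.csv"))
  write_population_csv(pop, paths[["population"]])
  write_epi_csv(epi, paths[["epi"]])
  write_cost_table_csv(tab, paths[["cost_table"]])
  invisible(paths)
}
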