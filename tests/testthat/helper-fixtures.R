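# Shared fixtures, built once per test run. Everything is generated in code;
# no files are read.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(build), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

default_pop <- function() {
  fixture("pop", generate_population(demographic_variant("G2L2W2")))
}

default_epi <- function() {
  fixture("epi", generate_epi_inputs(pop = default_pop(), seed = 2010))
}

default_cost_table <- function() {
  fixture("tab", generate_cost_table(cost_config(), default_epi(),
                                     default_pop(), seed = 2010))
}

default_profile <- function() {
  fixture("profile", suppressWarnings(baseline_per_capita(default_cost_table())))
}

# constant [101 x 31] rate matrix for single-stratum PDE/microsim work
const_surface <- function(value) matrix(value, 101L, 31L)

# internal array constructors, re-used heavily in tests
age_sex_array <- chronicost:::age_sex_array
age_sex_year_array <- chronicost:::age_sex_year_array
age_sex_type_array <- chronicost:::age_sex_type_array
age_sex_type_year_array <- chronicost:::age_sex_type_year_array

# a tiny complete cost table: one value per (field, diagnosis, sex, group)
toy_cost_table <- function(percap = 60, members = 10) {
  groups <- cost_age_groups()
  grid <- expand.grid(field = EXPENDITURE_FIELDS,
                      diagnosis = MODEL_DIAGNOSES, sex = MODEL_SEXES,
                      g = seq_len(nrow(groups)), stringsAsFactors = FALSE)
  df <- data.frame(field = grid$field, diagnosis = grid$diagnosis,
                   sex = grid$sex,
                   age_lo = groups$lo[grid$g], age_hi = groups$hi[grid$g],
                   total_cost_eur = members * percap / length(EXPENDITURE_FIELDS),
                   member_count = members)
  structure(df, class = c("aggregated_cost_table", "data.frame"),
            sample_fraction = 0.068)
}
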