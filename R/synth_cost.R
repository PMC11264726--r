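## Synthetic aggregated claims-cost table: total costs and member counts by
## expenditure field x diagnosis x sex x 5-year age group, emulating an
## aggregated random sample of a statutory-health-insurance population.
## Per capita age shapes are calibrated so that the all-ages per capita cost
## per sex and diagnosis equals configurable 2010 targets (defaults match
## published headline values).

#' The 22 five-year age groups of the claims dialect
#'
#' Groups run 0-4, 5-9, ..., 105-109. The model's age range stops at the
#' absorbing class 100, so the 21st group contains only age 100 and the 22nd
#' (nominally the open-ended 105+ class) is always empty.
#'
#' @return data.frame with integer columns `lo`, `hi`.
#' @export
cost_age_groups <- function() {
  lo <- seq(0L, 105L, by = 5L)
  data.frame(lo = lo, hi = lo + 4L)
}

#' Default configuration of the cost-table generator
#'
#' @param per_capita_target named numeric: all-ages per capita cost targets
#'   (euro per person-year, 2010) keyed `"<diagnosis>.<sex>"`.
#' @param noise_sd standard deviation of the log-normal noise applied per
#'   table cell (mean-one; 0 disables it).
#' @param sample_fraction sampling fraction of the emulated claims sample.
#' @return list consumed by [generate_cost_table()].
#' @export
cost_config <- function(per_capita_target = c(
                          T1.male = 4285, T1.female = 4889,
                          T2.male = 3868, T2.female = 3889,
                          none.male = 2360, none.female = 2316),
                        noise_sd = 0.02,
                        sample_fraction = 0.068) {
  if (sample_fraction <= 0 || sample_fraction > 1)
    stop("sample_fraction must be in (0, 1]", call. = FALSE)
  list(
    per_capita_target = per_capita_target,
    noise_sd = noise_sd,
    sample_fraction = sample_fraction,
    field_share = c(physicians = 0.17, dentists = 0.05, pharmacies = 0.18,
                    hospitals = 0.35, sick_benefits = 0.05, others = 0.20),
    # unit-scale per capita age shapes by diagnosis; the diabetes shapes are
    # multiples of the non-diabetic shape declining with age, so that
    # age-specific cost ratios fall with age (about 7-fold for type 1 in
    # childhood, 2-2.5-fold for type 2 in young adulthood, 1.2-1.4 at old
    # ages) while the member-weighted aggregate hits the calibration target
    age_shape = local({
      none <- function(a) 0.62 + 0.5 * exp(-a / 7) +
        0.55 / (1 + exp(-(a - 67) / 11))
      list(
        T1 = function(a) none(a) * (1.45 + 7.5 * exp(-a / 13)),
        T2 = function(a) none(a) * (1.25 + 2.2 * exp(-pmax(a - 18, 0) / 30)),
        none = none
      )
    })
  )
}

#' Generate a synthetic aggregated cost table
#'
#' Member counts per (diagnosis, sex, age-group) stratum are
#' `round(sample_fraction * N * p_diagnosis)` summed over the group's ages
#' in the base year. Stratum costs are members times a calibrated per capita
#' schedule times the expenditure-field share, with optional mean-one
#' log-normal noise. The per-diagnosis/sex level of the schedule is chosen
#' so the member-weighted all-ages per capita cost equals the configured
#' target, so downstream [baseline_per_capita()] aggregates land on the
#' targets (exactly, at zero noise).
#'
#' @param config see [cost_config()].
#' @param epi an `epi_inputs` object (base-year prevalence).
#' @param pop a `population_projection` covering 2010.
#' @param seed integer RNG seed for the noise.
#' @return data.frame of class `aggregated_cost_table` with columns `field`,
#'   `diagnosis`, `sex`, `age_lo`, `age_hi`, `total_cost_eur`,
#'   `member_count`; `sample_fraction` attached as an attribute.
#' @export
generate_cost_table <- function(config = cost_config(), epi, pop,
                                seed = 2010) {
  if (!inherits(epi, "epi_inputs")) stop("`epi` must be epi_inputs",
                                         call. = FALSE)
  if (config$sample_fraction <= 0 || config$sample_fraction > 1)
    stop("sample_fraction must be in (0, 1]", call. = FALSE)
  share <- config$field_share[EXPENDITURE_FIELDS]
  share <- share / sum(share)

  N0 <- pop[, , "2010"]
  p1 <- epi$prevalence0[, , "T1"]
  p2 <- epi$prevalence0[, , "T2"]
  pn <- pmax(1 - p1 - p2, 0)
  pdiag <- list(T1 = p1, T2 = p2, none = pn)

  groups <- cost_age_groups()
  ng <- nrow(groups)
  mid <- pmin((groups$lo + groups$hi) / 2, 100)

  rows <- vector("list", 0L)
  with_seed(seed, {
    for (d in MODEL_DIAGNOSES) {
      shape_g <- config$age_shape[[d]](mid)
      for (s in MODEL_SEXES) {
        members <- vapply(seq_len(ng), function(g) {
          ages <- intersect(groups$lo[g]:groups$hi[g], MODEL_AGES)
          if (!length(ages)) return(0)
          idx <- ages + 1L
          round(config$sample_fraction * sum(N0[idx, s] * pdiag[[d]][idx, s]))
        }, numeric(1))
        wmean_shape <- if (sum(members) > 0)
          sum(members * shape_g) / sum(members) else 1
        level <- config$per_capita_target[[paste(d, s, sep = ".")]] /
          wmean_shape
        percap_g <- level * shape_g
        for (f in EXPENDITURE_FIELDS) {
          noise <- if (config$noise_sd > 0) {
            exp(stats::rnorm(ng, 0, config$noise_sd) - config$noise_sd^2 / 2)
          } else rep(1, ng)
          rows[[length(rows) + 1L]] <- data.frame(
            field = f, diagnosis = d, sex = s,
            age_lo = groups$lo, age_hi = groups$hi,
            total_cost_eur = members * percap_g * share[[f]] * noise,
            member_count = members)
        }
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("aggregated_cost_table", "data.frame"),
            sample_fraction = config$sample_fraction, seed = seed)
}
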