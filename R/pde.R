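## Illness-death model (IDM) prevalence projection. The prevalence
## p(a, t) of an irreversible condition obeys the transport equation
##
##   (d/dt + d/da) p = (1 - p) * ( i(a,t) - p * (m1(a,t) - m0(a,t)) )
##
## where i is the incidence and m0/m1 the mortality of the non-diseased /
## diseased. Only general mortality m and the mortality rate ratio
## MRR = m1/m0 are observed, so the partition m = p*m1 + (1-p)*m0 gives
##   m0 = m / (1 + p*(MRR - 1)),  m1 = MRR * m0,
## hence m1 - m0 = m*(MRR - 1) / (1 + p*(MRR - 1)).
## The equation is integrated along characteristics (age and calendar time
## advancing together) with classical fourth-order Runge-Kutta; rate
## surfaces are interpolated bilinearly off-grid. Remission is zero.

# right-hand side along a characteristic, vectorised over characteristics
idm_rhs <- function(p, age, year, imat, mmat, rrmat) {
  i <- bilinear_at(imat, age, year)
  m <- bilinear_at(mmat, age, year)
  rr <- bilinear_at(rrmat, age, year)
  excess <- m * (rr - 1) / (1 + p * (rr - 1))
  (1 - p) * (i - p * excess)
}

# integrate one sex/type stratum; inputs are [101 x 31] matrices
solve_idm_pde_matrix <- function(p0, imat, mmat, rrmat, step) {
  nsub <- as.integer(round(1 / step))
  if (abs(nsub - 1 / step) > 1e-8)
    stop("step must divide one year evenly", call. = FALSE)
  h <- 1 / nsub

  # characteristics: 101 launched from the 2010 cross-section plus one per
  # later birth year starting at age 0 with p = 0
  a0 <- c(MODEL_AGES, -(1:30))
  p <- c(p0, rep(0, 30))
  P <- matrix(NA_real_, 101L, 31L,
              dimnames = list(age = as.character(MODEL_AGES),
                              year = as.character(MODEL_YEARS)))
  P[, 1L] <- p0

  u <- 0
  for (stepno in seq_len(30L * nsub)) {
    age <- a0 + u
    act <- age >= 0 & age <= 100           # alive cohorts inside the grid
    if (any(act)) {
      aa <- age[act]; tt <- 2010 + u; pp <- p[act]
      k1 <- idm_rhs(pp, aa, tt, imat, mmat, rrmat)
      k2 <- idm_rhs(pp + h / 2 * k1, aa + h / 2, tt + h / 2, imat, mmat, rrmat)
      k3 <- idm_rhs(pp + h / 2 * k2, aa + h / 2, tt + h / 2, imat, mmat, rrmat)
      k4 <- idm_rhs(pp + h * k3, aa + h, tt + h, imat, mmat, rrmat)
      p[act] <- clip01(pp + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4))
    }
    u <- stepno * h
    if (stepno %% nsub == 0L) {
      j <- as.integer(round(u)) + 1L
      age_now <- a0 + u
      on_grid <- age_now >= -1e-9 & age_now <= 100 + 1e-9
      rows <- as.integer(round(age_now[on_grid])) + 1L
      P[rows, j] <- p[on_grid]
    }
  }
  P
}

#' Project prevalence with the illness-death-model PDE
#'
#' Integrates the IDM transport equation along age-time characteristics from
#' a base-year (2010) prevalence cross-section, with boundary condition
#' `p(0, t) = 0` for later birth cohorts and zero remission. Output is
#' clipped to [0, 1].
#'
#' @param p0 initial prevalence: matrix `[age, sex]`, or array
#'   `[age, sex, type]` (one solve per type).
#' @param incidence,mortality_general,mrr rate surfaces
#'   `[age, sex, year 2010-2040]` (or `[age, sex, type, year]` matching
#'   `p0`'s types for incidence and mrr).
#' @param step integration step in years, in (0, 1]; must divide one year.
#' @return array `[age, sex, year]` (or `[age, sex, type, year]`) of
#'   prevalence.
#' @export
solve_idm_pde <- function(p0, incidence, mortality_general, mrr,
                          step = 0.25) {
  if (!is.numeric(step) || length(step) != 1L || step <= 0 || step > 1)
    stop("step must be in (0, 1]", call. = FALSE)
  for (x in list(incidence, mortality_general, mrr))
    if (any(is.na(x))) stop("NaN in rate surfaces", call. = FALSE)

  if (length(dim(p0)) == 3L) {  # per-type dispatch
    out <- age_sex_type_year_array()
    for (d in MODEL_TYPES) {
      out[, , d, ] <- solve_idm_pde(p0[, , d], incidence[, , d, ],
                                    mortality_general, mrr[, , d, ], step)
    }
    return(out)
  }
  if (any(p0 < 0 | p0 > 1)) stop("p0 must lie in [0, 1]", call. = FALSE)
  out <- age_sex_year_array()
  for (s in seq_along(MODEL_SEXES)) {
    out[, s, ] <- solve_idm_pde_matrix(p0[, s], incidence[, s, ],
                                       mortality_general[, s, ],
                                       mrr[, s, ], step)
  }
  out
}

#' Case counts from prevalence and population
#'
#' `count(a, s, d, t) = p(a, s, d, t) * N(a, s, t)`.
#'
#' @param prev prevalence array `[age, sex, type, year]`.
#' @param pop population array `[age, sex, year]`.
#' @return list with `counts` (the age-resolved array) and `totals`
#'   (`[type, sex, year]`, summed over ages).
#' @export
case_counts <- function(prev, pop) {
  check_common_grid(prev, pop, "prevalence", "population")
  counts <- age_sex_type_year_array()
  for (d in MODEL_TYPES) counts[, , d, ] <- prev[, , d, ] * pop
  totals <- apply(counts, c(3L, 2L, 4L), sum)
  names(dimnames(totals)) <- c("type", "sex", "year")
  list(counts = counts, totals = totals)
}
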