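## Stochastic microsimulation oracle for the PDE solver. Simulates birth
## cohorts through healthy -> ill -> dead transitions in small discrete time
## steps with the same m0/m1 mortality partition as the PDE (m0 computed
## from the cohort's current simulated prevalence). Individuals within a
## cohort are exchangeable, so state transitions are drawn as binomial
## counts, which is distributionally identical to an individual-level
## simulation but runs in O(steps) per cohort.

#' Microsimulation estimate of illness-death-model prevalence
#'
#' For each probe `(age, year)`, the birth cohort reaching that age in that
#' year is simulated from its entry into the model (the 2010 cross-section
#' with initial prevalence `p0`, or birth at age 0 for cohorts born after
#' 2010) until the probe point. Returns the prevalence among survivors with
#' a binomial standard error.
#'
#' @param incidence,mortality_general,mrr rate surfaces `[101 x 31]`
#'   (age 0-100 by year 2010-2040) for one sex/type stratum.
#' @param probes data.frame with numeric columns `age`, `year`; requires
#'   `year - age <= 2040` and probe points on or after 2010.
#' @param n individuals per cohort (>= 1000).
#' @param seed integer RNG seed.
#' @param p0 optional length-101 initial (2010) prevalence curve for cohorts
#'   alive in 2010; default all zero.
#' @param dt simulation time step in years (<= 0.1).
#' @return data.frame with columns `age`, `year`, `p_hat`, `se`,
#'   `survivors`.
#' @export
microsim_oracle <- function(incidence, mortality_general, mrr, probes,
                            n = 200000, seed = 1, p0 = NULL, dt = 0.1) {
  if (n < 1000) stop("n must be at least 1000", call. = FALSE)
  if (dt <= 0 || dt > 0.1) stop("dt must be in (0, 0.1]", call. = FALSE)
  if (!all(c("age", "year") %in% names(probes)))
    stop("probes need columns `age` and `year`", call. = FALSE)
  if (is.null(p0)) p0 <- rep(0, 101L)

  res <- probes[, c("age", "year")]
  res$p_hat <- res$se <- res$survivors <- NA_real_

  with_seed(seed, {
    for (k in seq_len(nrow(probes))) {
      a_star <- probes$age[k]; t_star <- probes$year[k]
      birth <- t_star - a_star
      if (birth >= 2010) {       # born inside the projection window
        a <- 0; t <- birth
        I <- 0; H <- n
      } else {                   # alive at the 2010 cross-section
        a <- a_star - (t_star - 2010); t <- 2010
        I <- stats::rbinom(1L, n, p0[round(a) + 1L])
        H <- n - I
      }
      nstep <- max(0L, as.integer(round((t_star - t) / dt)))
      for (st in seq_len(nstep)) {
        alive <- H + I
        if (alive == 0) break
        phat <- I / alive
        i <- bilinear_at(incidence, a, t)
        m <- bilinear_at(mortality_general, a, t)
        rr <- bilinear_at(mrr, a, t)
        m0 <- m / (1 + phat * (rr - 1))
        m1 <- rr * m0
        # healthy: competing incidence/death via total exponential hazard,
        # events allocated proportionally to the constituent hazards
        tot <- i + m0
        if (tot > 0 && H > 0) {
          events <- stats::rbinom(1L, H, 1 - exp(-tot * dt))
          newill <- stats::rbinom(1L, events, i / tot)
          H <- H - events
          I <- I + newill
        }
        if (m1 > 0 && I > 0)
          I <- I - stats::rbinom(1L, I, 1 - exp(-m1 * dt))
        a <- a + dt; t <- t + dt
      }
      alive <- H + I
      res$survivors[k] <- alive
      res$p_hat[k] <- if (alive > 0) I / alive else NA_real_
      res$se[k] <- if (alive > 0)
        sqrt(res$p_hat[k] * (1 - res$p_hat[k]) / alive) else NA_real_
    }
  })
  res
}
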