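test_that("pure ageing: zero mortality/fertility/migration shifts cohorts", {
  params <- new_demographic_variant("test", fertility = 1e-12,
                                    life_expectancy_2040 = c(male = 80,
                                                             female = 85),
                                    net_migration = 0)
  base <- default_base_counts()
  pop <- generate_population(params, base, mortality = 0)
  # interior diagonal identity N(a+k, t+k) = N(a, t); age 100 is absorbing
  for (k in c(1, 10, 30)) {
    expect_equal(pop[(1 + k):100, , 1 + k], base[1:(100 - k), ],
                 ignore_attr = TRUE)
  }
  expect_equal(sum(pop[1, , -1]), 0, tolerance = 1e-3)  # no newborns
})

test_that("huge mortality leaves newborns (and migrants) only", {
  params <- new_demographic_variant("test", fertility = 1.55,
                                    life_expectancy_2040 = c(male = 80,
                                                             female = 85),
                                    net_migration = 0)
  pop <- generate_population(params, default_base_counts(), mortality = 50)
  expect_lt(sum(pop[-1, , "2011"]), 1)     # everyone above age 0 is gone
  expect_gt(sum(pop[1, , "2011"]), 0)      # births still happen
})

test_that("default variant keeps the 2040 population within 10% of 2010", {
  pop <- default_pop()
  expect_equal(dim(pop), c(101L, 2L, 31L))
  expect_true(all(is.finite(pop)) && all(pop >= 0))
  ratio <- sum(pop[, , "2040"]) / sum(pop[, , "2010"])
  expect_gt(ratio, 0.9)
  expect_lt(ratio, 1.1)
})

test_that("all six demographic variants produce complete non-negative grids", {
  for (v in c("G2L2W2", "G2L2W1", "G2L2W3", "G1L2W2", "G2L1W2", "G2L3W2")) {
    pop <- generate_population(demographic_variant(v))
    expect_equal(dim(pop), c(101L, 2L, 31L))
    expect_true(all(is.finite(pop)) && all(pop >= 0))
  }
})

test_that("population generator validates inputs", {
  params <- demographic_variant("G2L2W2")
  expect_error(generate_population(params, default_base_counts()[1:50, ]),
               "ages")
  bad <- default_base_counts(); bad[3, 1] <- -1
  expect_error(generate_population(params, bad), "non-negative")
  expect_error(new_demographic_variant("x", 0, c(male = 80, female = 85), 0),
               "fertility")
  expect_error(new_demographic_variant("x", 1.5, c(male = 30, female = 85), 0),
               "life_expectancy")
})

test_that("epi generator hits the weighted prevalence targets", {
  pop <- default_pop(); epi <- default_epi()
  w <- pop[, , "2010"] / sum(pop[, , "2010"])
  t2 <- sum(w * epi$prevalence0[, , "T2"])
  t1 <- sum(w * epi$prevalence0[, , "T1"])
  expect_gt(t2, 0.065); expect_lt(t2, 0.075)
  expect_gt(t1, 0.0025); expect_lt(t1, 0.0035)
  expect_true(all(epi$prevalence0 >= 0 & epi$prevalence0 <= 1))
  expect_true(all(epi$incidence >= 0))
  expect_true(all(epi$mrr >= 0))
  expect_true(all(epi$mortality_general >= 0))
})

test_that("epi generator honours zero incidence and rejects bad shapes", {
  cfg <- epi_config()
  cfg$incidence_shape <- list(T1 = function(a) 0 * a, T2 = function(a) 0 * a)
  epi <- generate_epi_inputs(cfg, pop = default_pop())
  expect_true(all(epi$incidence == 0))

  cfg2 <- epi_config(target_prevalence = c(T1 = 0.003, T2 = 0.9))
  expect_error(generate_epi_inputs(cfg2, pop = default_pop()),
               "prevalence > 1")
})

test_that("cost table round-trips a constant per capita schedule exactly", {
  cfg <- cost_config(noise_sd = 0)
  cfg$age_shape <- list(T1 = function(a) rep(1, length(a)),
                        T2 = function(a) rep(1, length(a)),
                        none = function(a) rep(1, length(a)))
  cfg$per_capita_target <- c(T1.male = 777, T1.female = 777, T2.male = 777,
                             T2.female = 777, none.male = 777,
                             none.female = 777)
  tab <- generate_cost_table(cfg, default_epi(), default_pop())
  prof <- suppressWarnings(baseline_per_capita(tab))
  occupied <- prof$c > 0
  expect_true(all(abs(prof$c[occupied] - 777) <= 777 * 1e-9))
})

test_that("cost table respects the seed contract", {
  tab1 <- generate_cost_table(cost_config(), default_epi(), default_pop(),
                              seed = 1)
  tab1b <- generate_cost_table(cost_config(), default_epi(), default_pop(),
                               seed = 1)
  tab2 <- generate_cost_table(cost_config(), default_epi(), default_pop(),
                              seed = 2)
  expect_identical(tab1, tab1b)
  expect_false(isTRUE(all.equal(tab1$total_cost_eur, tab2$total_cost_eur)))
  # member counts are noise-free, hence seed-invariant
  expect_identical(tab1$member_count, tab2$member_count)
})

test_that("cost table structure matches the claims dialect", {
  tab <- default_cost_table()
  expect_equal(nrow(tab), 6 * 3 * 2 * 22)
  expect_true(all(tab$total_cost_eur >= 0) && all(tab$member_count >= 0))
  # member counts are shared across the six fields of a stratum
  split_counts <- tapply(tab$member_count,
                         paste(tab$diagnosis, tab$sex, tab$age_lo),
                         function(x) length(unique(x)))
  expect_true(all(split_counts == 1))
  expect_error(generate_cost_table(cost_config(sample_fraction = 0),
                                   default_epi(), default_pop()),
               "sample_fraction")
})

test_that("generators are deterministic given identical seeds", {
  p1 <- generate_population(demographic_variant("G2L2W2"), seed = 7)
  p2 <- generate_population(demographic_variant("G2L2W2"), seed = 7)
  expect_identical(unclass(p1), unclass(p2))
  e1 <- generate_epi_inputs(pop = p1, seed = 7)
  e2 <- generate_epi_inputs(pop = p2, seed = 7)
  expect_identical(e1, e2)
})
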