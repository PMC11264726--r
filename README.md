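# chronicost

Projection of chronic-disease prevalence and direct medical costs with the
illness-death model, built for the German type 1 / type 2 diabetes setting
(base year 2010, horizon 2040) and reusable for other irreversible chronic
conditions.

## Who this is for

Epidemiologists and health economists who need age- and sex-resolved
forecasts of how many people will live with a diagnosed chronic condition
and what their care will cost a payer, under explicit, deterministic
assumptions about incidence trends, mortality differentials, demographic
change and cost growth.

## The model

**Prevalence.** The illness-death model (IDM) has three states — healthy,
diseased, dead — with incidence *i(a, t)*, mortality *m₀* (healthy) and
*m₁* (diseased), no remission. Its age–time prevalence *p(a, t)* obeys the
transport equation

    (∂/∂t + ∂/∂a) p = (1 − p) · ( i − p · (m₁ − m₀) )

Only the general-population mortality *m* and the mortality rate ratio
MRR = m₁/m₀ are observed, so the partition m = p·m₁ + (1 − p)·m₀ gives
m₀ = m / (1 + p·(MRR − 1)). `solve_idm_pde()` integrates this along
age–time characteristics (4th-order Runge–Kutta, default step 0.25 y) from
the 2010 cross-section, with p(0, t) = 0 for later birth cohorts. A
binomial-count microsimulation (`microsim_oracle()`) provides an
independent stochastic check.

**Costs.** From an aggregated claims-style table (costs by expenditure
field × diagnosis × sex × 5-year age group), `baseline_per_capita()`
derives per capita cost curves c_d(a, s). Excess costs
e_d = c_d − c_none grow geometrically at an annual rate r while
non-diseased costs stay at their 2010 level:
c_d(a, s, t) = c_none(a, s) + e_d(a, s)·(1 + r)^(t−2010).
Totals are Σ N·p·c; the cost ratio is R = c_d / c_none; population
attributable costs follow

    PAC = p·(R − 1) / (1 + p·(R − 1))

aggregated by cost weighting (equivalently excess-over-total), and
extrapolated to national euros through the claims sampling fraction
(6.8 %).

**Scenarios.** `build_scenarios()` returns 16 deterministic futures: base
case (MRR −2 %/y), incidence trends ±1/±2/±5 %/y, constant prevalence,
cost growth 1 %/5 %/y, five demographic variants, and a "most probable"
combination (incidence +1 %/y, MRR −2 %/y, cost growth 1 %/y).

Because the original claims and demographic inputs are not public, the
package ships calibrated synthetic generators (`generate_population()`,
`generate_epi_inputs()`, `generate_cost_table()`) that emulate their
structure; see the methods vignette for what they do and do not emulate.

## Worked example

```r
library(chronicost)
specs  <- build_scenarios()
inputs <- prepare_inputs(specs[c("s1", "s16")], seed = 2010)
r16 <- run_scenario(specs$s16, inputs)   # most probable scenario

round(sum(r16$totals["T2", , "2010"]) / 1e9, 2)  # 22.22
round(sum(r16$totals["T2", , "2040"]) / 1e9, 2)  # 41.52
round(percent_change(r16), 1)                    # T1 110.9  T2 86.9
round(r16$per_capita[, "2040"])                  # T1 5570   T2 4279
```

In the synthetic world, total annual type 2 costs rise from €22.2bn (2010)
to €41.5bn (2040) under scenario 16 — +86.9 % — and annual per capita
costs of a person with type 1 / type 2 diabetes reach €5,570 / €4,279.
These are properties of the calibrated synthetic inputs, not reproductions
of any published projection; the 2010 calibration anchors (per capita costs
by sex/diagnosis, population prevalence ≈7 % type 2 / ≈0.3 % type 1) are
checked in `tests/testthat/test-acceptance.R`.

Command line (same pipeline):

```sh
exec/chronicost synth --out inputs --seed 2010
exec/chronicost run --out results --scenarios 1,9,10,16
exec/chronicost summarize --out results
```

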