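---
title: "Methods: illness-death-model cost projection and its synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: illness-death-model cost projection and its synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model and its assumptions

chronicost couples two deterministic components on a common grid of single
ages 0–100, sexes, diabetes types T1/T2 and calendar years 2010–2040.

**Prevalence dynamics.** The illness-death model treats diagnosed diabetes
as irreversible (remission rate 0): individuals move healthy → diseased at
incidence $i(a,t)$ and die at $m_0(a,t)$ (healthy) or $m_1(a,t)$
(diseased). Prevalence obeys

$$\left(\frac{\partial}{\partial t}+\frac{\partial}{\partial a}\right)p
  = (1-p)\,\bigl(i - p\,(m_1 - m_0)\bigr).$$

Routine data deliver general mortality $m$ and the mortality rate ratio
$\mathrm{MRR}=m_1/m_0$, not $m_0$ and $m_1$ themselves. We partition
$m = p\,m_1 + (1-p)\,m_0$, so
$m_0 = m/(1+p(\mathrm{MRR}-1))$ and $m_1-m_0 = m(\mathrm{MRR}-1)/(1+p(\mathrm{MRR}-1))$.
This keeps the diseased and non-diseased mortalities consistent with the
general population at every age and time.

Assumptions worth making explicit:

* prevalence of diagnosed disease at birth is zero — the boundary condition
  for cohorts born after the base year ($p(0,t)=0$);
* migrants carry the same prevalence as residents (no migrant-specific
  rates anywhere in the pipeline);
* calendar trends act multiplicatively per calendar year on the base-year
  rate surface: $x(a,s,t)=x(a,s,2010)(1+\delta)^{t-2010}$.

**Cost dynamics.** Per capita costs by diagnosis come from an aggregated
claims-style table. Only the *excess* $e_d = c_d - c_\mathrm{none}$ is
projected ($c_d(t) = c_\mathrm{none} + e_d (1+r)^{t-2010}$); non-diseased
per capita costs are frozen at 2010 because no defensible growth input
exists for them. Totals, the cost ratio $R=c_d/c_\mathrm{none}$, the
population attributable costs
$\mathrm{PAC}=p(R-1)/(1+p(R-1))$ and the national extrapolation follow
algebraically.

## Tunable parameters

| parameter | unit | default | rationale |
|---|---|---|---|
| PDE step | years | 0.25 | RK4 at 0.25 y reproduces the analytic stationary solution to <1e-13 and halving the step changes nothing at the 1e-4 level |
| incidence / MRR trends | proportion per year | scenario-specific (±1–5 %, −2 %) | the pinned scenario set |
| excess-cost growth $r$ | proportion per year | 0 / 0.01 / 0.05 | scenario set; 1 % is the moderate reading, 5 % an extreme upper bound |
| sampling fraction | proportion | 0.068 | the claims sample emulated by the generator |
| base-year targets | € per person-year | 4285/4889 (T1 m/f), 3868/3889 (T2), 2360/2316 (none) | published 2010 aggregates used as calibration anchors |
| prevalence targets | proportion | 0.003 (T1), 0.07 (T2) | published 2010 population prevalence |

## Numerical choices

* **Characteristics + RK4.** Age and time advance together, so the PDE
  reduces to one ODE per birth cohort; 131 cohorts (101 from the 2010
  cross-section, 30 later birth years) are integrated in a single
  vectorised sweep. Rates are interpolated bilinearly between grid nodes
  and clamped at the grid edges (age 100 is an open-ended class).
* **Clipping.** The solver clips $p$ into $[0,1]$ after every step; this
  only binds under deliberately extreme rates (tested) — for realistic
  inputs the dynamics keep $p$ interior.
* **MRR floor.** A declining MRR trend is floored at 1 wherever the
  base-year ratio is ≥ 1, preventing the excess mortality from changing
  sign over the horizon. Ratios already below 1 are left untouched.
* **Cost-ratio floor.** $c_\mathrm{none}$ is floored at €1 before division
  so degenerate synthetic inputs cannot blow up $R$; default inputs never
  hit the floor.
* **PAC clipping.** Strata with $R<1$ (protective) are clipped to
  $\mathrm{PAC}=0$, so attributable fractions are nonnegative.
* **Interpolation.** Epidemiological support points use natural cubic
  splines evaluated at integer ages with constant extrapolation beyond the
  outermost points; grouped cost data anchor each 5-year group at its
  midpoint with piecewise-linear interpolation. Natural boundary conditions
  leave a small edge error on strongly curved inputs (about 0.012 on a
  sine test sampled every 10 years) — inherent to the method, not a bug.
  Proportions are clipped to $[0,1]$, rates and costs to $[0,\infty)$
  after interpolation.
* **Determinism.** Every stochastic element (generator jitter,
  microsimulation) runs under an explicit seed with the caller's RNG state
  restored; identical configurations yield byte-identical CSV outputs.

## Design decisions where the design was open

* **Scenario 9/10 composition.** Described only as cost-robustness
  scenarios; implemented as base-case epidemiology (MRR −2 %/y) plus
  $r=1\%$ / $5\%$, matching how scenario 16 composes the same ingredients.
* **PAC aggregation.** The age/sex-specific PAC surface is aggregated by
  cost weighting: stratum attributable costs (stratum total × PAC, which
  equals the stratum excess identically) over stratum totals. A plain mean
  over ages would weight empty old-age strata equally with the populous
  ones and could not reproduce a worked €-extrapolation consistently.
* **National extrapolation.** "Dividing total costs by the sample size" is
  read as division by the sampling *fraction* (6.8 %) — the only reading
  on the national-euro scale.
* **Age groups.** The 22 five-year claims groups are taken as 0–4 …
  105–109. Modelled ages stop at the absorbing class 100, so group 21
  holds only age 100 and group 22 is structurally empty; the zero-member
  rule (per capita 0, warning) handles it, and because interpolation is
  midpoint-anchored the empty group only influences ages beyond 102, i.e.
  nothing on the model grid beyond a mild pull between ages 97 and 100.
* **Config format.** JSON (jsonlite) rather than YAML — no YAML reader is
  assumed at runtime.

## What the synthetic generators emulate — and what they do not

The original demographic projection and claims aggregates are not public,
so the generators reproduce their *statistical structure*, calibrated to
published 2010 headline values:

* `generate_population()` is a three-knob cohort-component model
  (fertility G, 2040 life expectancy L, net migration W with a fixed
  triangular age profile peaking at 25). Mortality is Gompertz–Makeham,
  rescaled yearly so period life expectancy moves linearly to the
  variant's 2040 target. It does **not** reproduce official variant
  outputs, cohort fertility schedules, or migration age structure by
  origin. The default 2010 pyramid is synthetic (≈81.8 M, bulge at 40–50).
* `generate_epi_inputs()` builds prevalence shapes (T1 rising through
  childhood to a plateau; T2 logistic in age), incidence and age-declining
  MRR curves, rescaled so population-weighted 2010 prevalence hits 0.3 % /
  7 % exactly before a 1 % log-normal jitter. Real claims surfaces have
  cohort effects, regional structure and coding artefacts that are not
  modelled.
* `generate_cost_table()` emulates the 6-field × 3-diagnosis × 2-sex ×
  22-group aggregate of a 6.8 % sample. Cost age shapes are chosen so the
  age-specific cost ratios fall with age (≈7-fold for T1 children,
  ≈2–2.5-fold for young T2 adults, 1.2–1.4 at old ages) while the
  member-weighted aggregate per capita costs land exactly on the 2010
  anchors (log-normal cell noise, σ = 0.02, mean one).

**Consequently**, a green test establishes that the *mathematics* of the
pipeline is right (analytic limits, oracle agreement, algebraic
identities, calibration anchors) — not that any euro projection for
Germany is reproduced. One quantitative gap is worth recording: with the
2010 per capita anchors fixed and age-declining cost ratios, the synthetic
world's aggregate attributable fractions in 2010 are ≈0.3 % (T1) and ≈3 %
(T2), well below the published 3.8 %/10.2 %. Reaching those would require
age-specific T2 excess costs of ≈€3.5k per case — incompatible with the
anchors unless the model's covered-cost base is much smaller than the full
insurance total. The published fractions therefore enter the worked
extrapolation as *inputs*, and no generator parameter was tuned toward
them.

## Known limitations

* Direct medical costs only; no indirect/productivity costs, no
  discounting, no comorbidity stratification.
* Scenarios 2–5 and 11–15 are documented defaults (the exact published
  definitions live in an unavailable supplement); they are configurable
  via `build_scenarios(config = ...)`.
* The constant non-diseased cost assumption makes long-horizon totals a
  conservative lower bound whenever background costs grow.
* Scenario bounds are deterministic envelopes, not confidence intervals.
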