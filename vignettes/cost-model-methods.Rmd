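---
title: "Methods: a prevalence-based cost-of-illness model for IPF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a prevalence-based cost-of-illness model for IPF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipfcoi)
```

## The model

Idiopathic pulmonary fibrosis (IPF) is a progressive fibrosing interstitial
pneumonia with highly variable natural history: some patients remain stable
for years, most worsen slowly, and a minority deteriorate rapidly. Because
management intensity tracks the disease course, `ipfcoi` computes the annual
direct healthcare cost per patient separately for each course and then
combines the courses by their population proportions.

The cost per patient-year in course $c$ is the sum of five components:

$$K_c = K^{\mathrm{diag}} + K^{\mathrm{tx}}_c + K^{\mathrm{mon}}_c +
        K^{\mathrm{exac}}_c + K^{\mathrm{eol}}_c$$

and the headline statistic is the course-weighted mean
$\bar K = \sum_c w_c K_c$ with $\sum_c w_c = 1$.

This is a *prevalence-based* cost-of-illness design: it attributes the costs
that prevalent cases generate within one year, from the payer (national
health system) perspective. Indirect and societal costs are out of scope.

### Diagnosis

The diagnostic work-up (visits, imaging, bronchoscopy, biopsies, function
tests) is a one-off cost $D = \sum_i q_i \, u_i$ (quantity × mean unit
cost). Only the newly diagnosed fraction of prevalent patients incurs it in
a given year, which in steady state is the incidence-over-prevalence ratio,
so

$$K^{\mathrm{diag}} = D \cdot \frac{I}{P}.$$

This component is identical across courses by construction — an invariant
the tests assert.

### Treatment

Per course: drug costs (fraction treated × unit price × daily dose ×
days/year of therapy, capped at 366), plus drug-related adverse events (AE),
plus non-pharmacological therapies (fraction × unit cost, e.g. lung
transplantation, pulmonary rehabilitation).

AE inclusion rules: only grade ≥ 3 events affecting **strictly more than
5 %** of treated patients are costed (an event at exactly 5 % is excluded;
the threshold is a function argument for users who want the boundary
included). Grade-3 events split between hospitalised and non-hospitalised
management by an explicit `hospitalized_fraction` input (default 0 — the
source tables carry both cost columns but never state the split); grade-4
events are always hospitalised.

### Monitoring

Resource-use profiles are declared over a period (typically 3 months, the
natural horizon of a quarterly follow-up schedule) and annualized per item
by $12/\text{period}$ — a quarterly profile counts four times a year, with
no seasonality.

### Acute exacerbations

One event costs $E = E_{\mathrm{diag}} + E_{\mathrm{tx}} +
E_{\mathrm{follow}}$ (differential diagnosis, treatment, resource use and
follow-up), identical for all courses; the annual component is $E \times
r_c$ with $r_c$ the course's events per patient-year.

### End-of-life care

End-of-life care (palliative treatment plus outpatient visits) is a lump
cost $L$ per dying patient. It is distributed over patient-years by the
annual mortality rate, approximated by DEALE (Declining Exponential
Approximation to Life Expectancy): the annual mortality rate is the
reciprocal of remaining life expectancy,

$$\mu_c = \min\!\left(\frac{12}{S_c}, 1\right), \qquad
  K^{\mathrm{eol}}_c = L \cdot \mu_c,$$

with $S_c$ the course's median survival in months. We use the *plain
reciprocal*, not the exponential-risk transform $1 - e^{-\mu}$: only the
reciprocal reproduces all three reference mortality rates (18.2 %, 28.6 %,
80 % from 66, 42, 15 months) at one-decimal rounding, and it is the textbook
DEALE statement. Survivals below 12 months are capped at a rate of 1 (a
patient dies at most once).

## Calibrated overrides: what is computed and what is pinned

The bottom-up engine (resource blocks × unit costs × fractions) is fully
implemented and validated against a brute-force flat-enumeration oracle on
randomized fixtures. The shipped baseline, however, pins the per-course
treatment, monitoring and exacerbation components to their published annual
values via the `overrides` block, for two reasons:

1. the unit costs and dose/duration inputs behind those cells were published
   only in supplementary material that is not available, and
2. the published per-course exacerbation costs are not exactly
   `event cost × printed rate` (the source evidently used unrounded internal
   rates), so recomputing them from the printed one- or two-digit rates
   cannot reproduce the published table.

Diagnosis and end-of-life are computed live through the annualization-ratio
and DEALE chains. The synthetic unit costs in the baseline catalogue are
plausible 2013 Spanish tariffs, clearly flagged in the fixture metadata,
with the diagnostic block calibrated so its one-off total is €4,736.28
(four times the annualized €1,184.07). A consequence worth knowing:
sensitivity scenarios on blocks that feed a pinned component (e.g.
monitoring resource use in the baseline) show no effect there — remove the
overrides (set `inputs$overrides <- NULL`) to exercise the computed route.

The end-of-life cells computed here differ from the published ones by 1–2
cents (241.27 vs 241.28, etc.): the source's lump sum was itself a rounded
print of unrounded components. At the euro level every aggregate agrees.

## Rounding

All arithmetic is double precision and unrounded; rounding is applied only
at display/write boundaries, half away from zero (`round_half_up()`), 2
decimals for euro amounts, 0 decimals for case counts.

Category shares are an exception worth documenting: independently rounding
each share to one decimal gives 4.5/27.0/22.5/44.1/**1.8** % — which does
not sum to 100.0 and does not match the reference presentation
(…/**1.9** %). `format_shares()` therefore uses largest-remainder
(sum-preserving) rounding: floor all shares at the displayed precision, then
distribute the remaining mass to the largest remainders. This reproduces the
reference shares exactly and always sums to 100.0. `category_shares()`
itself returns unrounded percents.

## Sensitivity analysis

Strictly one-at-a-time: each scenario perturbs exactly one parameter block
(returning a modified copy — the baseline is never mutated) and the
course-weighted TOTAL is recomputed at the block's minimum and maximum.
Epidemiological estimates use ±25 % multipliers; resource-use and unit-cost
blocks substitute their stored min/max columns (`qty_min`/`qty_max`,
`cost_min`/`cost_max` — elicitation ranges are user inputs; the shipped ones
are synthetic). Percent differences are stored unrounded and displayed as
integers. The tornado ranking sorts by the larger absolute percent
difference, ties broken alphabetically. A useful exact duality: multiplying
prevalence by $k$ rescales only the diagnosis component, by $1/k$, because
prevalence enters the per-patient model solely through $I/P$. No
probabilistic (Monte Carlo) analysis is provided by design.

## The synthetic Delphi panel

`generate_panel()` emulates a three-round expert elicitation: each of
`n_experts` (default 15, a realistic national expert pool for an orphan
disease) answers each question with multiplicative log-normal noise around
the question's generating value, truncated to admissible bounds — costs and
rates are positive and right-skewed, so log-normal is the natural noise
model. In round $r$ the dispersion shrinks to
$\sigma \cdot f^{\,r-1}$ (convergence factor $f$, default 0.5): after group
feedback, responses cluster ever more tightly around the shared estimand,
and the running median converges.

A design note: we deliberately do **not** re-anchor round-$r$ draws on the
round-$(r{-}1)$ median. Re-anchoring turns the consensus into a random walk
seeded by the round-1 median, making its sampling error permanent — the
round-3 median would then sit ~5 % away from the generating value in a
substantial share of panels, defeating the parameter-recovery property the
generator exists to provide. With shrinking dispersion around the estimand,
the round-3 median recovers the generating value within 5 % in well over
95 % of panels at the default settings (asserted by simulation in the test
suite).

Consensus is the per-question median (midpoint of the central pair for even
panels); the agreement rate is the share of experts within a relative
tolerance band (default ±20 %) of the round median — a stated proxy, since
real panels rarely define their consensus metric. `panel_to_inputs()`
writes consensus values back into a model-input template by dot-path
(e.g. `courses.rapid.median_survival_months`) and re-validates.

What a green synthetic-panel test does *not* establish: anything about real
expert behaviour — bias, anchoring on the questionnaire wording, dropout
(one expert leaving after round 1 is not simulated), or correlated errors
across questions. The generator's job is strictly to exercise the pipeline
and to verify parameter recovery as noise vanishes.

## Degenerate inputs and numerical choices

* Course proportions must sum to 1 within 1e-9; an empty course list is a
  validation error.
* Incidence above prevalence is allowed with a warning (the ratio then
  exceeds 1); zero prevalence is a domain error.
* Unreferenced unit-cost entries warn (shared catalogues are expected);
  dangling `resource_id`s are reference errors.
* Zero-dispersion panels are handled exactly (no `rnorm` call), so
  "dispersion → 0 recovers the template" holds to the last bit.
* All validation failures carry classed conditions
  (`ipf_validation_error`, `ipf_reference_error`, `ipf_io_error`,
  `ipf_domain_error`), which the CLI maps to distinct exit codes.

## Worked example

```{r example}
inputs <- baseline_inputs()
tab <- build_breakdown_table(inputs)
tab

case_counts(inputs$epidemiology)[1:2]

format_shares(category_shares(tab[1:5, "weighted"]))

run_univariate(inputs, baseline_scenarios())
```

## Known limitations

* The baseline's treatment/monitoring/exacerbation cells are calibrated
  inputs, not bottom-up computations (see above); only synthetic fixtures
  exercise the full computed route end-to-end.
* National burden is per-patient cost × case count only; no demographic
  projection.
* Single currency, single year; no inflation adjustment or conversion.
* DEALE is a constant-hazard approximation; no life tables or parametric
  survival.
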