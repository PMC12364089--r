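---
title: "Modelling frailty onset and progression in an ageing population"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling frailty onset and progression in an ageing population}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frailtyflow)
```

## The model

`frailtyflow` implements a compartmental (stock-flow) simulation of frailty
in adults aged 50 and over. The population is stratified into 16 subgroups:
four age bands (50–64, 65–74, 75–84, 85+) crossed with four frailty states
defined from the electronic frailty index (eFI), a cumulative deficit score
$e = d/36$ where $d$ is the number of recorded deficits. Scores are
categorised as Fit ($e \le 0.12$), Mild ($0.12 < e \le 0.24$), Moderate
($0.24 < e \le 0.36$) and Severe ($e > 0.36$).

Each subgroup $i$ carries an alive stock $N_i(t)$ plus cumulative died,
left and entered accounting stocks — $3 \times 16 = 48$ stocks in all —
linked by 72 flows: per-subgroup entry, death and de-registration (16
each), frailty progression to the next state (12; none out of Severe) and
ageing to the next band (12; none out of the open-ended 85+ band). The
annual update is a synchronous difference equation: with flow proportions
$p^{death}_i(t), p^{dereg}_i(t), p^{prog}_i(t), p^{age}_i(t)$ applied to
the start-of-year stock,

$$N_i(t+1) = N_i(t)\,(1 - p^{death}_i - p^{dereg}_i - p^{prog}_i -
p^{age}_i) + \text{inflows}_i(t) + E_i(t),$$

where inflows come from the fitter neighbouring state and the younger
neighbouring band, and $E_i(t)$ is the exogenous entry count.

Key structural assumptions:

* **Irreversibility.** Frailty transitions are one-directional and
  adjacent-state only (Fit → Mild → Moderate → Severe). Reversals observed
  in routine data are rare and partly scoring artefacts, so the model
  omits them; this is asserted structurally on the built flow table.
* **Ageing chain.** The average age within a band is assumed unchanged
  between timesteps, so a single ageing proportion per subgroup moves
  people to the next band (the usual "blending" simplification of
  ageing-chain models; the 50–64 band, being widest, is most affected).
* **Annual clock.** Observations are annual snapshots (eFI recomputed each
  1 January), so the default clock is a one-year difference equation. A
  sub-annual Euler mode (`dt < 1`, per-step proportion $1-(1-p)^{dt}$) is
  available for sensitivity checks; it reproduces the annual survival
  exactly for constant rates and is not the default.

## Flow rate specifications

Each flow is either a constant proportion or a polynomial in model time
$t$ (years since the calibration origin), $p(t) = \beta_0 + \beta_1 t +
\beta_2 t^2 + \beta_3 t^3$, clamped to $[0,1]$ at evaluation (entry flows
are counts, clamped below at 0). Polynomial rates are **frozen at
`t_max`**, the last calibrated time: projecting beyond the data window
holds transition rates constant, because unfrozen cubic extrapolation
diverges and the baseline scenario is explicitly "rates stay as last
observed".

If a subgroup's four outflow proportions jointly exceed 1 they are
rescaled proportionally to sum to 1 (with a warning). The data give no
within-year ordering of competing outcomes, so the synchronous, symmetric
treatment is the only reproducible choice.

## Calibration

`calibrate()` estimates all 72 flows from an annual observation table
(`year, band, state, alive_start, deaths, deregs, entries, ageing_out,
progression_out`). Proportions are formed as flow count divided by
start-of-year alive (matching the snapshot structure of the data; years
with an empty subgroup are excluded with a warning) and fitted by ordinary
least squares on the raw scale. The polynomial degree (0–3) is chosen by
*forward nested F-tests at α = 0.05*: the degree is raised only while the
added term is significant. The stopping rule is strictly forward, so a
curve whose quadratic term is masked by its cubic can stall at degree 1 —
the per-flow selection trace is kept in `calibration_report()` precisely
so users can inspect and override individual forms in configuration.
Entries are fitted on raw counts, since entry is an exogenous inflow with
no source stock. Proportions are fitted untransformed rather than on the
logit scale: the estimator then has a closed form (degree 0 is the
arithmetic mean), and boundary excursions are handled by clamping at
simulation time.

## Validation

Fit is scored by the mean absolute percentage error over the overlapping
years, one cell per variable per applicable subgroup — Alive, Entering,
Dying, Deregistration for all 16 subgroups, plus 12 Ageing and 12
FrailtyTransition cells: 88 cells. Stocks are compared at the start of
every overlapping year including year 0 (which contributes 0 when initial
conditions are copied from the observations); flows on within-year totals.
Zero-observed points are excluded with a warning rather than producing
infinite cells in small subgroups. The overall summary weights every
variable equally, interpreted as the *flat unweighted mean of all 88
cells*; this interpretation reproduces the published internal-validation
summary (7.06%) to within 0.03 percentage points when recomputed from the
published 2-dp cells (7.09%), whereas averaging per-variable-class means
does not (≈ 7.3%). Both modes are implemented (`weighting = "flat"` is the
default). The corresponding external-validation recomputation gives 9.40%
against a published 9.53%; the residual discrepancy (rounding, or a
different cell subset) is documented and nothing in the package is pinned
to it.

For transfer to an external cohort, `rescale_parameters()` multiplies the
entry and de-registration specifications by constant factors (both
constant values and polynomial coefficients scale linearly; factors of 0
close the model), and `scale_initial_prevalence()` re-splits each band's
initial total across frailty states to target shares, preserving band
totals — the adjustment used when the validation population's deprivation
profile shifts its baseline prevalence.

## National scale-up

`national_parameters()` zeroes entries and de-registrations (net migration
assumed negligible at national scale: people enter only by turning 50 and
leave only by dying), and `project_population()` drives the closed model
with a projection table of people reaching age 50 each year, added to the
youngest band before each annual step. The frailty mix of 50-year-old
entrants is not observed; it is a configurable `entry_split`, by default
derived from the youngest band's composition (`split_from_state()`), with
an all-Fit option. The choice is logged by the CLI because it materially
affects 50–64 prevalence. National initialisation uses band-level
population totals split by cohort prevalence shares; single-year-of-age
initialisation is not attempted (the underlying data are banded).

`summarise_population()` reports the aggregates used for headline results:
total 50+ population, per-subgroup shares, the frail (Mild or worse) count
and percentage, the moderate-plus-severe count, and each band's share of
the frail population. Counts are reported to the nearest person, totals
additionally to the nearest thousand, percentages to 1 dp.

## The synthetic-cohort generator

Real primary-care cohort extracts are not redistributable, so the
package's test bed is a generator with known ground truth emulating their
structure. Per subgroup-year, the competing outcomes (die / de-register /
progress / age / stay) are one multinomial draw on the start-of-year alive
count with the year's true proportions; entries are Poisson. Generation is
aggregate-level rather than individual-level: it is orders of magnitude
faster and exercises every downstream stage, which consume aggregates
anyway. A single seeded stream fixes the entire output.

The default stated world (`example_parameters()`) uses initial
distributions from the published cohort tables
(`table1_initial_state()`, e.g. 46.8% of an English-style cohort in
(50–64, Fit)); annual death proportions rising from 0.4% (50–64, Fit) to
≈ 38% (85+, Severe); ageing at the reciprocal of band width; frailty
progression of 3–9% per year graded by band and state; de-registration a
flat 3%; and entry intensities of 5% of the initial subgroup stock per
year. These are one-time choices of plausible magnitudes for a UK 50+
primary-care population, not fitted values. What a green test establishes
is therefore that the pipeline recovers *a* known world of realistic
shape, not that it reproduces any particular cohort: the generator has no
secular trends unless the supplied truth is polynomial, no overdispersion
by default (a Dirichlet-multinomial `dispersion` multiplier is exposed),
no demographic waves like the baby-boom bulge, and no reporting artefacts.

`table1_initial_state()` rounds quota shares with a largest-remainder
correction so stocks sum exactly to the cohort size; because the printed
percentages sum to slightly over 100%, quotas are renormalised first when
the discrepancy exceeds what fractional rounding can absorb (only relevant
for cohorts ≫ 10^5). Ties are broken towards larger subgroups.

## Numerical and degenerate-input choices

* eFI boundary scores exactly at 0.12/0.24/0.36 are assigned to the less
  frail category (intervals closed above); the printed intervals have gaps
  and the source handling is unstated, so this is a documented convention,
  chosen because it reproduces the printed cut-offs on every score of the
  form $k/36$.
* Conservation (alive + died + left = initial + entered) is maintained to
  float precision; sub-float negative stocks arising from exact-rescale
  arithmetic are truncated at 0, and anything beyond rounding tolerance is
  an internal error.
* Fewer than two calibration points yield a constant spec equal to the
  mean, with a warning; noiseless series short-circuit the F-test ladder
  via an exact-fit tolerance of $10^{-12}\times$ total sum of squares.
* MAPE of an all-zero observed series is an error, not 0 or infinity.

## Known limitations

The model inherits the simplifications of its design: no covariates beyond
age and frailty (gender, deprivation and ethnicity enter only through
upstream rate adjustment or scalar rescaling), no migration, no reversals,
banded ages with the blending bias that implies, and baseline projections
that hold post-calibration rates constant. The acceptance suite reproduces
every published aggregate that is a pure function of printed numbers; the
published end-to-end projections themselves cannot be regenerated because
the fitted parameter values and source cohorts are not public — the
package treats all fitted forms as configuration.
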