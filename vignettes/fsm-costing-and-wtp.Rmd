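---
title: "Costing rural fecal sludge services and estimating willingness to pay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Costing rural fecal sludge services and estimating willingness to pay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fsmplan)
```

This vignette documents the models behind `fsmplan`, the assumptions and
parameter conventions they rest on, and the design choices made where the
problem left them open. The running example is Bhaluka subdistrict,
Bangladesh, whose parameters ship as the package default
(`bhaluka_scenario()`).

## 1. Demand model

A planning area holds `n_latrines` single-pit latrines, each used by
`users_per_latrine` people who each add `accumulation_rate` litres of
sludge per day. A pit of effective volume `pit_volume` litres therefore
fills every

    emptying_interval = pit_volume / (users * rate * 365)   [years]

and the whole stock generates `n_latrines / emptying_interval` emptying
events per year, each of `pit_volume` litres. Demand is assumed uniform
over the year with no seasonality and no heterogeneity in pit size or
fill state; the model is linear in the stock, so sub-areas can be
costed separately and summed.

Volumes are carried in litres throughout the computation and converted
to cubic metres only for reporting, to avoid unit drift between the
technology tables (litres) and headline results (m³).

**Effective vs nominal parameters.** The Bhaluka measured accumulation
rate is 0.11 L/person/day, but the subdistrict's planning totals
(15,219 m³/yr and 20,760 events/yr over 77,413 pits with 5 users each)
are mutually consistent only with an *effective* rate of 0.1077
L/person/day and an *effective* per-event volume of 733.1 L. The default
stock uses the effective pair, so the pipeline reproduces the planning
totals to better than 0.05%; both values are plain arguments and can be
overridden (e.g. `bhaluka_scenario(accumulation_rate = 0.11)`). We do not
attempt to derive the effective pit volume from pit geometry (ring count
and diameter under-determine it without a ring height), so volume is
exposed directly.

## 2. Fleet sizing

Each option combines an emptying technology (manual crews: 30 + 150 min
per pit, 3-person crew; diaphragm pump: 15 + 20 min, 1 operator) with a
haul mode:

* **direct** — 120-L barrel trucks drive the full village-to-subdistrict
  route (3.5 km track at 10 km/h plus 8.9 km road at 30 km/h each way);
* **transfer** — trucks shuttle village-to-union (3.5 km track) and
  15,000-L tankers run union-to-subdistrict (8.9 km road), with the
  transfer station itself treated as costless.

A trip takes the round-trip travel time plus one handling event at each
end (`load_time` minutes each, i.e. 30 + 30 min for a truck, 60 + 60 min
for a tanker). This "two handling events per trip" reading of the single
loading/emptying time in the technology table is a deliberate modelling
decision: it treats loading at the pit and unloading at the destination
as equally expensive, and it is the convention under which the sized
fleets land exactly on the published Bhaluka counts (49 manual teams, 10
diaphragm units, 228 direct trucks, 169 + 3 in transfer mode).

Annual trips per stage are `annual_volume / capacity`, kept fractional:
trips are an accounting device for hours and kilometres, and rounding
them per-vehicle or per-day would bake a utilisation assumption into the
arithmetic. Only unit counts are rounded, upward, against the work
calendar (8 h × 4 d × 40 wk = 1,280 h/yr by default):
`units = ceiling(task_hours / 1280)`. In transfer mode both stages carry
the full annual volume; barrel-to-tanker batching mismatches are
ignored. Tankers have no track speed (`NA`) and error out if routed over
track. Staffing multiplies the standing fleet by crew sizes — a sized
unit is crewed even when not fully utilised — while labour *cost* is
charged on task hours only (below).

`weighted_average_distance()` aggregates per-union distance tables into
planning averages for users with their own weights; the package default
legs (3.5, 8.9 km) are the published population-weighted averages taken
as authoritative inputs, because the underlying population weights are
not published (an unweighted village-count average of the same table
gives 3.17 km, not 3.5).

## 3. Cost model

Annual cost decomposes exactly into three parts:

* **Annualised capital** — per-unit BDT/yr values from the technology
  tables (manual 156; diaphragm 3,909; truck 46,124; tanker 154,003),
  covering capital servicing, capital maintenance and wear and tear over
  a 25-year horizon. These are *inputs*: no single discount-rate
  convention reproduces all four published values (implied rates range
  from ~5% to ~10%), so we take them as given rather than pretend to
  derive them. `npv_annualize()` offers the internally consistent
  alternative — purchases at years 0, r, 2r, … discounted at the scenario
  rate (11% default), summed and divided by the horizon — and is off by
  default; for the manual kit it gives 139.9 BDT/yr, not the published
  156, which is why it is an option rather than the default. Wear and
  tear is treated as already folded into the per-unit values and is not
  double-counted in operating cost.
* **Labour** — task hours × crew hourly rate (crew rates derive from
  composition and wages: 2 × 20 + 15 = 55 BDT/h for a manual crew,
  20 for a diaphragm operator, 35 for truck and tanker crews). Charging
  the standing fleet's full 1,280 h/yr instead would inflate labour by
  roughly 1% and is not what the published costs do.
* **Operating** — annual round-trip kilometres × per-km rate, with
  `rate = fuel_use × fuel_price + consumables` (6.9 BDT/km trucks,
  15.6 BDT/km tankers at 68 BDT/L fuel).

Computation stays in BDT; USD mirrors divide by a fixed 78 BDT/USD at
report time. `round_cost_report()` applies display rounding (whole BDT
and USD; two decimals for per-household USD). Tariffs divide total
annual cost by events (per emptying event) or by all latrines (flat
subscription per household-year and -month). Under the defaults the four
options cost 45.8M, 25.7M, 42.7M and 22.6M BDT/yr — every published cost
cell is matched within 0.5% (the residual is spreadsheet rounding in the
source figures, mostly in the direct-haul operating cells), capital
totals exactly.

## 4. Willingness-to-pay estimator

The double-bounded dichotomous-choice model assumes household *i*'s
latent willingness to pay is

    WTP_i = x_i' beta + e_i,   e_i ~ N(0, sigma^2),

with `x_i` an intercept plus optional household covariates. The response
pair to base bid `b1` and follow-up `b2` brackets `WTP_i`:
yes/yes → `[b2, ∞)`, yes/no → `[b1, b2)`, no/yes → `[b2, b1)`, and no/no
→ `(−∞, b2)`. Each household contributes the log of the normal
probability of exactly one interval, weighted by its frequency weight,
giving an interval-censored normal likelihood maximised over
`(beta, log sigma)`.

**The no/no convention.** A common textbook statement of the no/no
outcome bounds WTP below by zero while its likelihood term
`1 − Φ((x'β − b2)/σ)` is the *untruncated* `P(WTP < b2)`. The package
implements the untruncated formula by default — the likelihood as
actually maximised — and exposes `truncate_at_zero = TRUE` to bound the
no/no interval at zero for analysts who want the stricter reading. The
synthetic generator correspondingly allows negative latent draws.

**Optimisation.** BFGS on `(beta, log sigma)` (so σ > 0 by construction)
with numerical gradients, relative tolerance 1e-10 on the objective, and
two starts: a least-squares initialiser on interval pseudo-midpoints
(open intervals get a midpoint one bid-spread beyond their finite
bound) and a dispersed start at the mean base bid with doubled scale;
the best converged maximum wins. Branch probabilities are floored at
1e-12 inside the objective; a fit whose optimum sits on the floor warns.
Identification requires at least two distinct response intervals — with
one interval σ is unbounded below — and perfectly collinear covariate
*columns* are dropped with a warning (rows are kept; survey software
that instead drops observations will report slightly different n).
Mean WTP is the weight-averaged linear predictor `mean(x)'beta`, with a
delta-method standard error from the inverse observed information; the
normal CI is `mean_wtp ± 1.96 × se`. Weights enter as frequency weights
(a weight-2 household counts as two); the default is unweighted.

The single-bound check (`fit_sbdc()`) discards the follow-ups and fits a
probit of the first response on `(x, b1)`; mean WTP is recovered as
`−mean(x)'beta_r / beta_bid`. Its standard error should exceed the
double-bounded one on the same data — the follow-up halves the interval
each response pins down — and a large gap between the two point
estimates flags starting-point anchoring.

`bootstrap_wtp()` resamples households (or whole villages with
`cluster = "village_id"`, reflecting two-stage cluster sampling),
refits, and reports the replicate SD as the SE, a normal CI around the
full-sample point, and a bias-corrected (BC, not accelerated) percentile
CI. Failed or non-converged replicates are dropped and counted, never
silently imputed. Every stochastic function in the package requires an
explicit seed.

`sample_size_cv()` implements the standard design-based calculation
`n = ⌈z² p(1−p) / m² × deff × (1 + nonresponse)⌉`. The defaults — p =
0.5, 95% confidence, design effect 2 for village clustering, 5%
non-response — reproduce the Bhaluka survey's n = 807 with a 5% margin
of error; the margin is a documented default rather than a published
fact, because 0.05 is the unique conventional value consistent with 807.

## 5. Synthetic surveys: what they do and do not show

`simulate_survey()` draws surveys from the estimator's own model: exact
arm sizes per bid vector (286/280/282/243 by default), households spread
over 44 village clusters, latent normal WTP, responses derived
mechanically from the latent draw. Covariates reproduce the Bhaluka
sample's published moments — household size 4.56 ± 1.71, annual income
USD 1,246 ± 1,078, education shares, 67% non-farm income, 68% brick
walls, 97% metal roofs — using families chosen by us, since only moments
are published: shifted binomial for under-dispersed counts, shifted
negative binomial for over-dispersed ones, log-normal income, Bernoulli
binaries. The default truth is intercept-only, mean 507 BDT and
σ = 200 BDT; σ is our calibration, chosen so simulated response-share
tables are qualitatively similar to the observed ones, and is
user-overridable.

Because the generator *is* the model, passing recovery tests
demonstrates internal consistency — the MLE finds the truth that
generated the data, CIs attain nominal coverage, the double-bounded SE
beats the single-bound SE — but says nothing about protest zeros,
anchoring, interviewer effects, non-normal tails or misreported income
in real surveys. The one contact with real data is the observed
response-count table (`bhaluka_response_counts()`): an intercept-only
fit to it gives mean WTP 506.6 BDT, within 0.05% of the published
covariate-adjusted 506.66, which is reassuring but partly fortuitous —
the published fit used household covariates that are not public, so
exact reproduction is impossible and the package's acceptance tests
treat ±10% as the meaningful band, with a dense grid search as the
optimiser's independent oracle.

## 6. Financing gap

`financing_gap()` reports coverage `100 × wtp / cost_per_event` on
unrounded values, and the deficit on whole-BDT rounded values
(`round(cost) − round(wtp)`), matching how tariff gaps are quoted;
under the defaults: 47% coverage, BDT 581 deficit per event, about BDT
12.06 million (USD 155,000) per year, against a full-cost subscription
of BDT 24 (USD 0.31) per household-month. Negative deficits (WTP above
cost) are reported as negative, not clipped, and the least-cost option
is used unless the caller passes a specific one.

## 7. Numerical choices, problem sizes and limitations

Tests and validation run at the survey's own scale (n = 1,091; 100
recovery replicates; 100 bootstrap replicates), which completes in well
under a minute per study on a single core. Degenerate inputs fail loudly
rather than silently: zero accumulation or pit volume, zero-hour
calendars, track legs for trackless vehicles, zero vehicle capacity,
all-identical responses, zero bid coefficients and non-positive σ all
raise errors; a zero-latrine stock is valid and flows zeros through
demand and fleet sizing but refuses to quote tariffs.

Known limitations: no vehicle routing or scheduling below annual-hours
granularity; no transfer-station or treatment-plant costs and no
resource-recovery revenue; no spike/zero-inflation or non-normal WTP
distributions (no Turnbull bounds); anchoring is diagnosed, not
modelled; sampling weights beyond frequency weighting (e.g.
design-consistent variance) are out of scope — use the village-cluster
bootstrap for clustered uncertainty.
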