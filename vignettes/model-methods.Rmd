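---
title: "Model structure, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cadprs` is a deterministic stock-and-flow cohort model of acute coronary
events (ACE) in a national adult population, built to evaluate polygenic
risk score (PRS) screening strategies. This vignette documents the model's
structure, the parameters that matter, the synthetic data that stand in
for non-public national calibration sources, and the design decisions made
where the modelling problem was genuinely open.

## Population stratification

The adult (20+) population is partitioned into 10,368 homogeneous risk
cells: sex (2) × age band (6: 20–34, 35–44, 45–54, 55–64, 65–74, 75+) ×
total cholesterol (3 levels × treated/untreated) × HDL (2) × systolic
blood pressure (4 levels × treated/untreated) × diabetes status (normal
glucose regulation, impaired glucose tolerance, type 2 diabetes) × smoking
(never/ex/current). Within each cell, persons occupy one of six
compartments: the primary-prevention pool, four post-ACE high-risk stocks
(years 1–2 since the event × whether it involved an out-of-hospital
cardiac arrest), and a prior-CHD pool. Two sub-stocks of the primary pool
track who has ever been PRS-tested (a one-off test; the stock is
absorbing) and who is on a statin because of a high PRS.

Counts are real-valued expectations: the model propagates deterministic
flows, which is what makes baseline-versus-scenario differences exact
rather than Monte-Carlo noisy. `synthesize_population()` also offers a
`"multinomial"` mode that draws integer counts once at initialisation,
seeded, for sensitivity checks on sampling variability.

## Risk engine

Each categorical level maps to a configurable representative continuous
value (defaults: ages 27/40/50/60/70/80 years; TC 180/220/260 mg/dL; HDL
40/60 mg/dL; SBP 115/130/145/165 mmHg). The level cut-points of the
original survey stratification are not published, so these are explicit
modelling choices, not estimates.

The 10-year risk uses the published sex-specific Framingham 2008
general-CVD Cox model, shipped as a validated CSV fixture
(`inst/extdata/framingham_2008_coefficients.csv`: log-covariate betas,
10-year baseline survival, aggregate mean linear predictor). Choices:

* **Horizon conversion.** Annual probabilities come from constant-hazard
  conversion, `1 − (1 − p)^(1/h)`; the 5-year Framingham score that gates
  PRS eligibility is hazard-scaled from the 10-year risk because the
  fixture carries only 10-year baseline survival. The method is recorded
  in the `"horizon_method"` attribute of `framingham_risk()` output.
* **Mapping gaps.** The Framingham equation has no term for impaired
  glucose tolerance or ex-smoking; both map to the reference level by
  default and are switchable in `default_representative_values()`.
* **Calibration.** The original model was calibrated to national death and
  hospitalisation records that are not available; `calibrate()` implements
  the reconstruction — per age×sex multipliers `observed/modelled`,
  defaulting to 1 — and its fixed-point behaviour is tested. Absolute
  event counts produced with multipliers of 1 on the synthetic population
  are therefore not comparable to any real country's burden.
* **Age extrapolation.** Bands 20–34 and 75+ fall outside the Framingham
  derivation range; their representative ages (27, 80) extrapolate the
  equation. The 20–34 band exists mainly to feed ageing; the 75+ band is
  where much of the chronic burden sits, so its risks should be read as a
  calibration target, not a prediction.

## PRS stratification and treatment

A high PRS means the top quintile (`top_fraction = 0.20`). Given a cell
probability `p` and odds ratio `OR` (default 1.9, CI 1.8–2.0) the package
solves `odds(p_high) = OR · odds(p_low)` subject to the mixture constraint
`f·p_high + (1−f)·p_low = p` with vectorised bisection on `p_low ∈ [0, p]`
(80 halvings; the mixture residual is asserted below 1e-12; the equation
is monotone so the bracket is exact, and `OR < 1` is handled with the
complementary bracket). An independent `uniroot` oracle cross-checks the
solver in the tests.

Statin treatment of a high-PRS person sets their annual probability to
`p_low`, the non-top-quintile risk — consistent with the roughly 46–48%
relative risk reduction reported for top-quintile carriers. An explicit
relative-risk-reduction mode (`treated_risk_mode = "rrr"`, default RRR
0.47) is available but off by default. With `OR = 1` the decomposition
collapses and every intervention is exactly inert, which the tests use as
a null check.

## Annual cycle

Within a simulated year, in order: (1) screening — eligible untested
persons attend per the scenario's Heart Health Check uptake, pass the
5-year-FRS gate (≤ 15% by default; ≤ 10% for the low-risk programme
variant; waived in the maximal scenario), are referred and tested; 20% of
tests return high-PRS and the prescription rate of those start statins;
(2) adherence — covered person-years are the statin stock times the
age/sex adherence fraction; (3) events — incident ACEs in the primary pool
(PRS-mixture rates, treated stratum at `p_low`), recurrent ACEs in the
high-risk stocks (annualised from the 25% two-year probability,
`1 − √0.75 ≈ 0.134`/year) and in the prior-CHD pool (primary risk × a
secondary-prevention multiplier, default 2.0, floor 1); (4) acute
outcomes — a fraction of events (default 0.12) become OHCAs with initial
survival 0.30, the rest face 30-day mortality 0.10; (5) excess high-risk
mortality — the post-ACE stocks' mortality is the age/sex base rate times
1.425 (men, non-OHCA), 1.495 (women, non-OHCA) or 3.9 (OHCA), capped at 1;
only the excess over base is counted here (and booked as ACE deaths), the
base being applied uniformly in the demography step, so base mortality is
never double-counted; (6) graduation — year-1 survivors to year-2, year-2
survivors to prior-CHD, this year's event survivors into year 1;
(7) demography — base non-ACE mortality on every compartment, fractional
ageing (1/15 per year out of 20–34, 1/10 out of the ten-year bands,
carrying tested/treated status proportionally), inflow of 20–34-year-olds,
and net migration scaled across each age×sex stratum.

Whether recurrent events also pass through the OHCA split is not
determined by the published description; the default says yes
(`recurrent_events_split_ohca`), configurable. Survivors of a recurrent
event restart the two-year high-risk clock. People who enter the post-ACE
stocks mid-year receive base mortality that year and the multiplied rate
in subsequent years.

Person conservation — `persons(t+1) = persons(t) + inflow + migration −
ACE deaths − non-ACE deaths` — holds to first-order float error and is
asserted at 1e-6 relative tolerance every simulated year in the tests.

## Scenarios

`builtin_scenarios()` encodes the three implementation strategies as data:
maximal (35+, no FRS gate, referral and prescription 1, full adherence,
no discontinuation), intermediate (45–74, full HHC attendance, FRS ≤ 15%,
referral 1, prescription 0.75, graded adherence) and targeted (HHC uptake
0.05/year at 45–54 and 0.20/year at 55+, PRS at 45–74 with FRS ≤ 15%,
referral 0.75, prescription 0.75, graded adherence). "Over 35" and
"45–75" map to whole age bands (35–44+ and 45–74 respectively). The
HHC uptake applies each year to the still-untested pool, so the targeted
scenario's reach compounds over the horizon. Setting the targeted
scenario's uptake and referral to 1 reproduces the intermediate scenario
exactly — a config-equivalence identity used as a test.

The survey-derived adherence table the design calls for is not public:
`default_adherence_table()` is a synthetic placeholder (0.50–0.80 in men
and 0.55–0.85 in women, rising with age) with 5%/year discontinuation.
People who would no longer pass the FRS gate remain on treatment
(treatment persistence); testing is once per lifetime.

## Economic evaluation

All flows are valued in AU$. Fixed published unit values: statin therapy
A$203.92/person-year, PRS test A$147.20 (US$100 at a frozen conversion),
willingness to pay A$50,000/QALY. Synthetic placeholders: acute event cost
A$28,000 (ambulance + hospital + rehabilitation bundle, chosen so the
baseline run's healthcare cost per case has the reported
tens-of-thousands-of-dollars magnitude) and chronic prior-CHD care
A$1,800/person-year.

Nine measures are computed against the matched baseline run: scenario
healthcare costs (acute + chronic + statin pharmacy — statins sit inside
healthcare costs, so net cost captures them automatically), PRS cost, net
cost (= scenario healthcare − baseline healthcare + PRS cost), QALYs
gained, value of QALYs (= QALYs × A$50,000 / 1e6, exact by construction),
cost per QALY (= net cost × 1e6 / QALYs; undefined and reported as `NA`
when no QALYs are gained), net benefit (= value − net cost, exact by
construction), and ACE deaths and cases averted. Additive measures
decompose exactly by sex; ratio measures are recomputed per sex.

The QALY model is a reconstruction — the published description does not
state one: averted deaths × remaining quality-adjusted life expectancy at
the age/sex of death (synthetic QALE table, 45→7 QALYs in men and 48→8 in
women across the age bands), plus averted non-fatal events × 0.08 QALYs,
plus averted prior-CHD person-years × 0.06 QALYs/year. Discounting
defaults to 0%, matching the exact QALY-value identity in the reported
tables; a positive rate is configurable. Because the utility model is
reconstructed and the population synthetic, tests target identities,
null-effects and monotonicity rather than absolute QALY counts.

The odds-ratio sensitivity bracket reruns the entire pipeline at OR 1.8
and 2.0 and reports per-measure min/max. Internal arithmetic is never
rounded; rounding to whole $m and whole QALYs is purely presentational.

## What the synthetic generator does and does not emulate

It emulates: a high-income adult age/sex structure (~20.6M persons by
default), plausible age-trending prevalence margins for each risk factor,
age/sex-graded non-ACE mortality, inflow and net migration, and an
age-graded prior-CHD seed (0–15%). Risk factors are sampled
*independently* within age×sex strata — the real joint distribution
(e.g. smoking–SBP correlation) is not represented, so cell-level joint
prevalences are not realistic even where the margins are. Socio-economic
and Indigenous-status stratification, implementation costs, and
beyond-horizon (lifetime) PRS benefit are out of scope. Consequently,
passing tests demonstrate the correctness of the model's mechanics and
the robustness of its qualitative cost-effectiveness ordering, not the
absolute burden or cost figures for any real population.

## Numerical choices and problem sizes

Bisection tolerance 1e-12 (asserted, error on failure); probabilities
clipped to `[0, 1−1e-12]` before annualisation; `p = 1` inputs rejected as
infinite hazards; zero-modelled-event calibration strata flagged and left
at multiplier 1; degenerate prevalence margins (a level at 100%) are
legal and empty the complementary cells. The test suite runs the full
10,368-cell model over 10-year horizons for the acceptance properties
(about 1–2 s per simulated decade) and uses closed three-or-fewer-cell
cohorts in the 75+ band (where ageing is zero) for ledger-oracle
equivalence at 1e-9; reduced populations of 0.3–2M persons are used where
only ratios and orderings matter, since runtime depends on the number of
cells, not persons.
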