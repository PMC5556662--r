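---
title: "Case-finding algorithms for incident cancer in claims data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case-finding algorithms for incident cancer in claims data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncoclaims)
```

## The problem

Claims data from statutory health insurance record diagnoses as they are
billed, not as they arise. Three properties make incident-case
ascertainment hard:

1. **Left censoring.** A person's disease history before their observable
   enrollment is invisible, so a first *observed* diagnosis may be a
   prevalent or recurrent case.
2. **Quarter resolution.** German outpatient diagnoses are assigned to
   calendar quarters, not days, so all windows in this package are quarter
   windows on the linear index `4 * year + (quarter - 1)`.
3. **Unconfirmed coding.** Outpatient diagnoses carry a mandatory
   certainty marker (G certain, V suspected, Z status post, A excluded),
   and a sizeable share of cancer codes — reported proportions range from
   roughly 16 to 32% depending on site and validation rule — is never
   confirmed by later claims.

The case definition implemented here addresses each point with one
parameter: an index diagnosis in the study year, a diagnosis-free
**lookback** of `L` years, and a confirmatory event within `C` quarters.

## The algorithm family

A case for site *s* (breast C50, women; prostate C61, men; colorectal
C18–C21, both sexes; matching is on the 3-character ICD-10 category,
case- and dot-insensitive) is a cohort member with:

* **Index**: an earliest study-year quarter containing a G-coded
  outpatient diagnosis or a main hospital discharge diagnosis of *s*.
  Inpatient stays are assigned to their discharge-date quarter, because
  the discharge diagnosis describes the reason for the admission.
* **Lookback**: no qualifying diagnosis of *s* in quarters
  `[index − 4L, index − 1]`. Here G- *and* Z-coded outpatient diagnoses
  and main *and* ancillary inpatient diagnoses qualify: a prevalent case
  under surveillance is typically Z-coded, and restricting the washout to
  "certain" codes would let it through.
* **Confirmation**: with `C = 0` no event is required. Otherwise either a
  second qualifying diagnosis in `[index + 1, index + C]` (same qualifying
  set as the lookback), or death in `[index, index + C]` unless the
  variant excludes death, or — in the surgery-required variants — a
  site-specific surgery in `[index, index + C]`.

The grid `algorithm_grid()` contains the 15 variants actually studied:
`L1-C1` … `L7-C1`, `L1-C4`, `L7-C4`, `L1-C0`, `L7-C0`, `L1-C1-ed`,
`L7-C1-ed`, `L1-C4-su`, `L7-C4-su`. Surgery variants are undefined for
prostate (no surgical class is a reliable marker of a new prostate
diagnosis under watchful waiting), and requesting that combination raises
an incompatibility error.

### Window conventions and tie-breaks

Several boundary choices are genuinely open; the package fixes them as
follows and treats them as part of the algorithm definition:

* The diagnosis-confirmation window **excludes the index quarter**
  (`[index + 1, index + C]`). Outpatient claims within one quarter are not
  reliably distinct encounters, so a same-quarter record can never confirm
  its own index — this also makes "the index diagnosis never confirms
  itself" structural rather than a bookkeeping rule.
* Death and surgery confirmation use `[index, index + C]` **including**
  the index quarter: a person who dies or is operated on in the index
  quarter cannot produce a later second diagnosis, and excluding such
  fulminant or immediately treated cases would bias the case mix.
* Surgery in the `-su` variants is **necessary and sufficient**: a second
  diagnosis or death does not rescue an unoperated candidate. This is the
  strict reading of "surgery as required confirmatory event" and produces
  the intended high-specificity variant.
* Only the **earliest** qualifying study-year quarter is evaluated per
  person and site. Any later index would fail the lookback against the
  earlier diagnosis anyway, since index-qualifying diagnoses are a subset
  of lookback-qualifying ones.
* When outpatient and inpatient records share the earliest index quarter,
  the case is reported as outpatient-indexed (a deterministic tie-break
  for the descriptive `index_setting` field only; it affects no counts).
* V- and A-coded diagnoses are ignored in every context.

A person can contribute one case per site, and one case to each of two
sites (breast/colorectal for women, prostate/colorectal for men).

## Cohort and denominators

Eligibility is assessed on the reference date (2013-01-01): the preceding
`required_years` (7 in the main analysis) must be continuously insured,
where continuity tolerates uncovered runs of at most 28 days — a gap of
*more than* 28 days breaks it. Gap length is counted as wholly uncovered
calendar days strictly between covered days, and coverage must include the
reference date itself. Persons with missing sex, missing birth year,
missing/invalid state or foreign residence are excluded; the tally
attributes each person to the *first* failing rule in that fixed order, so
exclusion counts are deterministic and sum with the cohort to the input
count.

Eligibility is deliberately not conditioned on coverage *after* the
reference date: the cohort is a closed population on the reference date,
and denominators are person counts (cumulative-incidence design, no
person-time). Two sensitivity regimes are available in
`run_sensitivity_analysis()`: a minimum of 1 year of continuity, and a
per-lookback regime where each algorithm's cohort requires continuity of
at least its own lookback length, giving seven denominators for L1–L7.

## Incidence estimation

Crude cumulative incidence is `100000 · n / N`. Age standardisation is
direct: `ACI = Σ_g w_g (n_g / N_g)` over the 18 five-year bands
0–4 … 85+, with the 1976 European Standard Population weights
(8000, 7000 × 10, 6000, 5000, 4000, 3000, 2000, 1000, 1000 per 100,000;
they sum to exactly 100,000 and the constructor asserts it). Age is
`study year − birth year`, the only age available in a data model that
carries birth years, not birth dates; against a registry standardising on
exact age at diagnosis this can shift band membership by at most one band
for persons whose birthday falls after diagnosis, a discrepancy we accept
and flag here. Bands with an empty denominator contribute 0 with a single
collective warning; a band with cases but no denominator is a data error.

All internal values are unrounded; `round_report()` applies the
half-away-from-zero one-decimal convention of printed incidence tables at
the reporting layer only, so no rounding error accumulates through
percent-difference chains.

## The synthetic study population

`sim_config()` defines the default conditions: 50,000 insured persons
observed 2006–2014 with study year 2013, an adult-skewed age pyramid
(mean age near 50), 60.5% women, a federal-state mix proportional to
state populations, small rates of missing demographics (sex ~2.6 × 10⁻⁶,
birth year ~6.9 × 10⁻⁵, state ~0.45%, foreign residence ~0.28%), and an
enrollment model in which 8% of persons enter late, 3% exit early and 10%
have one coverage gap whose geometric length (mean 22 days) leaves roughly
a quarter of gaps over the 28-day continuity limit.

Ground truth is generated *before* coding: per site, an age-dependent
quarterly onset hazard, a prevalent-at-start probability, recurrence among
prevalent cases (geometric latency, mean 16 quarters), and an excess
case-fatality hazard after onset (highest for colorectal cancer), all on
top of a Gompertz-like background mortality. The coding layer then
produces what the algorithms actually see:

* the onset quarter is coded with probability 0.92 (30% of coded indexes
  as inpatient main-discharge records);
* follow-up quarters are G-coded with probability 0.85 each for three
  quarters, then Z-coded at 0.25 per quarter — so a 1-quarter confirmation
  captures most but not all true cases, and a 4-quarter window captures
  nearly all, reproducing the observed moderate case gain from longer
  confirmation periods;
* prevalent cases are Z-coded at 0.15 and (erroneously) G-coded at 0.03
  per quarter — sparse enough that short lookbacks miss some of them,
  which is precisely the false-positive channel longer lookbacks remove;
* truly incident cases carry a spurious earlier G code with probability
  0.08 (workup or miscoding before true onset), the channel that makes
  longer lookbacks *lose* a little sensitivity;
* disease-free persons receive a single V-coded (suspected-only) diagnosis
  with per-person probability ~0.01, and rare A-coded noise; benign
  non-cancer diagnoses (mean 2 per person) surround the cancer codes;
* breast and colorectal episodes are operated with probability 0.70/0.65
  within ~120 days (recurrences at half that rate); 25% of prostate cases
  follow watchful waiting with follow-up coding reduced to 0.20.

Where the emulated setting supplies no quantitative estimate, these values
were chosen once as plausible for the setting and are not fitted; the
resulting share of unconfirmed outpatient cancer coding falls in the
reported 16–32% range. `sim_config_perfect()` switches every noise channel
off and codes every onset in its own and the following quarter, giving the
closed-form calibration case: the fraction of persons truly incident in
the study year is governed by `1 − (1 − h)⁴` for a flat quarterly hazard
`h`.

Determinism: generation is fully vectorised under a single seeded RNG
stream, so a fixed `(config, seed)` reproduces the tables bit-identically.
We chose this over per-person RNG streams keyed by `(seed, person_id)`
because the package's reproducibility contract is at the dataset level and
a single stream keeps the generator two orders of magnitude cheaper;
the cost is that output is only invariant for an identical configuration
(including `n_persons`), not person-by-person across configurations.

What the simulator does **not** emulate: real German age pyramids or
regional incidence gradients, billing/cost fields, comorbidity coding,
second primaries within one site, tumour stage, and any correlation
between coding quality and provider. Passing tests on synthetic data
therefore demonstrate the *logic* of the algorithms and estimators — not
that any particular algorithm is well calibrated for real SHI claims.

The registry-style benchmark (`generate_registry_benchmark()`) standardises
ground-truth study-year onsets over all persons with known demographics
and German residence, regardless of insurance continuity — an idealised,
complete registry for the simulated population. Claims-based estimates
are compared to it with `compare_benchmark()`.

## Validation metrics

With ground truth, each identified case is a true positive
(`INCIDENT_2013`) or a false positive (prevalent, recurrent,
suspected-only, incident in another year, or disease-free); truly incident
cohort members not identified are false negatives. `validation_metrics()`
reports TP/FP/FN, sensitivity and PPV per site and algorithm. In the test
suite these metrics are required to move monotonically along the chain
`L1-C1 → L7-C1 → L7-C4-su` — sensitivity non-increasing with a strict
overall decrease, PPV non-decreasing with a strict overall increase. The
non-strict step comparisons are deliberate: at realistic case counts
(tens of true cases in a 50,000-person population) adjacent steps of a
nearly saturated metric can tie, and demanding strictness at every step
would test sampling noise rather than the mechanism.

## Numerical and testing choices

* Problem sizes: property tests run the engine against an independent
  brute-force oracle on hundreds of random populations of up to 20
  persons; behavioural and recovery tests use populations of 50,000
  persons (generation takes about a second, the full 15-algorithm grid a
  few seconds).
* Stochastic checks are run at fixed seeds with 95% binomial or
  4-standard-error bounds on closed-form expectations; with several sites
  checked per run, occasional boundary misses at a given seed are expected
  behaviour of the design, not evidence of bias (the generator's totals
  are verified unbiased separately).
* Monotonicity properties (case counts non-increasing in lookback length,
  non-decreasing in confirmation length, surgery-required sets nested in
  their unrestricted counterparts, no-confirmation sets containing every
  confirmed variant) are structural consequences of the window logic and
  are asserted on every simulated dataset.
* Degenerate inputs: empty claims tables, cohorts with zero eligible
  persons and algorithm/site incompatibilities all return typed empty
  results or classed errors (`oncoclaims_config_error`,
  `oncoclaims_data_error`, `oncoclaims_incompatible_error`), never partial
  output.

## Known limitations

* Procedures are modelled as abstract classes (`LUMPECTOMY`, `MASTECTOMY`,
  `ENDOSCOPY`, `COLORECTAL_SURGERY`, `OTHER`); mapping real OPS/EBM codes
  to these classes is the user's responsibility on real data.
* Age at standardisation is year-difference age (see above).
* The simulator's parameters are plausible, not fitted; absolute synthetic
  incidence levels should not be read as population estimates.
* Confidence intervals for ACI are out of scope, as are record linkage,
  person-time denominators and trend analysis.
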