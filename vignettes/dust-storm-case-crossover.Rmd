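---
title: "Methods: dust-storm detection and case-crossover estimation with intermittent speciated monitoring"
author: "dustcase"
output: rmarkdown::html_document
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Dust storms raise ambient particulate matter sharply for a day or two.
Estimating their short-term effect on emergency department (ED) visits is
complicated by how dust days are observed: speciated aerosol networks such
as IMPROVE sample on a 1-in-3 or 1-in-6 day schedule, so the exposure is
intermittent, and "dust day" itself must be inferred from the chemical
composition of the filter, not from storm reports. `dustcase` implements
the complete analysis chain for this setting:

1. a five-criteria classifier that labels each measured site-day as dust
   storm (1), non-dust (0), or missing;
2. distance-buffer linkage of ZIP units to monitors;
3. ICD-9/ICD-10 outcome ascertainment of ED visits;
4. a customized time-stratified case-crossover design whose strata are
   built to align with the monitor sampling cycle; and
5. weighted conditional logistic regression with analytic derivatives,
   reporting lag-specific odds ratios (lags 0–5) with Wald intervals.

A synthetic-data module generates all four input streams with known
ground truth so that every stage, and the chain end to end, can be
validated by parameter recovery.

# Dust-day classification

A sampled site-day is a dust storm day when all five criteria hold:

1. **High mass**: PM10 ≥ `pm10_min` and PM2.5 ≥ `pm25_min` (defaults
   30 and 4 µg/m³).
2. **Coarse-dominated size split**: PM2.5/PM10 ≤ `ratio_max` (default
   0.45). Wildfire smoke, the main confusable event type, is
   fine-dominated.
3. **High crustal elements**: Si + Ca + K + Fe + Ti ≥ `crustal_min`
   (default 1.2 µg/m³). A per-element mode is available because "high
   crustal concentrations" is ambiguous between a joint and an aggregate
   test; the aggregate is the default since crustal composition varies
   by source region.
4. **Low anthropogenic species**: each of As, Zn, Cu, Pb, SO4, NO3, OC,
   EC at or below its ceiling. Ceilings are absolute concentrations by
   default; a fraction-of-PM2.5 mode is provided because the convention
   differs between published implementations of composition screens.
5. **Low crustal enrichment**: for Zn, Cu, Pb and K, the enrichment
   factor EF = (C_el/C_ref)_sample ÷ (A_el/A_ref)_crust must be at or
   below `ef_max` (default 10, the conventional ceiling below which an
   element is considered crustal in origin). The reference element is Fe
   and the crustal abundances are average upper-continental-crust mass
   fractions, shipped as an editable table.

Conventions fixed here and relied on by the tests: **all comparisons are
inclusive** (a value exactly at a floor or ceiling passes); the label is
0 as soon as any criterion fails on *present* inputs, even when other
inputs are missing; the label is missing only when a criterion that
would otherwise decide the label cannot be evaluated. Records violating
PM2.5 ≤ PM10 are flagged, never silently corrected. Unsampled days are
coded missing by `classify_series()`.

The published description of this screen states the five criteria
qualitatively; the numeric thresholds live in the original algorithm's
implementation and are not public. They are therefore configuration
values here, with defaults calibrated once so that a composition profile
like the dust-day means of the source network (PM10 ≈ 59 µg/m³, fine
fraction ≈ 0.21, fine Si ≈ 2 µg/m³, near-crustal trace-metal ratios)
labels 1 and a clean rural background profile labels 0.

A monotonicity property is tested: raising Si, Ca, Fe or Ti, or lowering
As, Zn, Cu, Pb, SO4, NO3, OC or EC, can never flip a label from 1 to 0
(and the reverse moves never flip 0 to 1). Potassium is excluded from
the perturbation suite by design: K appears in criterion 3 (where more
K helps) and in criterion 5's numerator (where more K hurts), so no
monotone direction exists for it. Fe is safe to perturb because it is
the enrichment reference: more Fe helps both criteria 3 and 5.

# Exposure linkage

ZIP units are modelled as discs (centroid + effective radius); "wholly
or partially within the buffer" becomes min(0-clamped centroid distance
minus radius) ≤ buffer, inclusive. Distances are great-circle on a
sphere of radius 6371 km — at a 50 km buffer the difference from
ellipsoidal distance is sub-kilometre and immaterial. Among sites whose
buffer a ZIP touches, the smallest *centroid* distance wins ("closest
monitor" most naturally refers to the ZIP's location, and the disc
boundary is an abstraction); exact ties break lexicographically on
site id, which is documented behaviour rather than an arbitrary
accident. The 15 km buffer used for sensitivity analyses is the same
code path.

# Outcome ascertainment

Built-in outcome groups: all respiratory disease (ICD-9 460–519 /
ICD-10 J00–J99), asthma (493 / J45), COPD (491, 492, 496 / J41–J44),
all cardiovascular disease (390–459 / I00–I99), ischaemic heart disease
(410–414 / I20–I25), dysrhythmia (427 / I47–I49), and congestive heart
failure (428 / I42, I50, I51). A visit matches if *any* diagnosis code,
primary or secondary, matches; ranges are compared on the 3-character
category (zero-padded numeric for ICD-9, letter-block ordinal for
ICD-10) and category prefixes by string prefix. The ICD era is 9 before
2015-10-01 and 10 from that date; a code whose alphabet contradicts the
date era is matched by its alphabet and flagged, because billing noise
is expected and silent drops hide bugs. A visit in several subgroups
appears in each subgroup's run independently; outcomes are analysed
separately.

# The customized time-stratified design

Conventional time-stratified case-crossover matches referents on year,
month and day of week. That is impossible here: with 1-in-3/1-in-6
sampling the exposure is not observed on the same weekday every week.
Instead each day is keyed to a stratum by

```
offset = days since analysis start
stratum = (floor(offset / 24), offset mod 6)
```

so every full stratum holds 4 days at 6-day intervals (span 18 days,
within a 24-day window), every day belongs to exactly one stratum, and
referent days fall both before and after case days on average. The
anchor is the configured analysis start date, so analyses with different
periods (e.g. a state whose records begin later) get their own strata.
Terminal partial blocks may produce smaller strata; singleton strata are
dropped because a set needs at least one referent.

Each case contributes one matched set over its stratum's dates. The dust
indicator at the analysis lag is attached to every member; **a set is
dropped whole if any member's lagged indicator is missing** (the
strictest reading of dropping "strata with missing dust storm
information"), and likewise for missing lagged meteorology. Because the
6-day within-stratum spacing is a multiple of the 3- and 6-day sampling
intervals, a stratum's member days are either all sampled or all
unsampled at any fixed lag — the design aligns with the monitoring
schedule by construction, and each lag analyses its own slice of the
calendar. Dropping is per-lag, since each lag is a separate model.

Identical sets (same member dates, exposure vector, covariate matrix and
case position) are collapsed into one weighted set; the conditional
likelihood is unchanged and the weighted and exploded representations
agree to 1e-10 in the tests. The pipeline pre-aggregates same-ZIP,
same-day visits for the same reason.

# The conditional logistic model

For matched set *s* with members *i*, case *c(s)*, covariate rows
*x_i* and weight *w_s*, the log-likelihood is

```
l(beta) = sum_s w_s [ x_c(s)' beta - log sum_i exp(x_i' beta) ]
```

Covariates: the dust indicator at the analysis lag (the target term),
six day-of-week indicators (Sunday reference), a holiday indicator,
linear + squared + cubic daily maximum temperature and mean dew point at
the same lag as the dust indicator, and optionally linear PM2.5, NO2 and
O3 terms at that lag. Day-of-week and holiday indicators are evaluated
at the **member date** — they adjust visit-day behaviour — while
meteorology is lagged with the exposure; the choice is switchable
(`lag_dow`) because only the meteorology convention is pinned down
externally.

Numerics: Newton–Raphson from beta = 0 with step-halving, exact analytic
gradient and Hessian, convergence when the gradient infinity norm falls
below 1e-8 × total set weight, at most 100 iterations — deterministic.
Continuous covariates are centred and scaled internally before the
polynomial terms enter the solver (centring is absorbed by the
conditional likelihood; scaling conditions the Hessian) and coefficients
are mapped back to the original scale. Terms with no within-set
variation are aliased to `NA`; a dust term with no discordant set at all
is a non-identifiability error naming the term. Complete separation is
flagged when a standardized coefficient exceeds 15 in magnitude while
the gradient has not vanished, and the odds ratio is then withheld
rather than reported as a large finite number. A singular information
matrix falls back to pseudo-inverse standard errors with a warning.
Wald intervals use 1.96·SE at the default 95% level; per-lag estimates
are reported without multiplicity adjustment, matching how such lag
profiles are conventionally presented. The default holiday calendar is
the fixed-date US federal holidays; floating holidays can be supplied as
a date vector.

An independent implementation (`survival::coxph`, exact method) is used
in the test suite as a cross-check oracle on shared fixtures —
coefficients and standard errors agree to 1e-6 — and a brute-force grid
search over the scalar-exposure likelihood confirms the optimizer to the
grid resolution. Neither stands in for the package's own fitter.

# What the generator emulates — and what it does not

`sim_config()` defaults define the validation conditions:

* **Monitor stream**: per-site 1-in-3 (or 1-in-6) day sampling; each
  sampled day is a dust day with probability `p_dust = 0.05`. This is
  roughly an order of magnitude more frequent than the ~0.6% dust-day
  rate of the rural network the package emulates: the compression gives
  desk-scale simulations (2 sites × 6 years) a few hundred discordant
  sets, enough to inform the fit, while leaving dust days rare. PM10,
  the PM2.5/PM10 fraction and 13 species are drawn per regime from
  lognormals. Medians follow the published dust/non-dust means where
  printed (PM10 59 vs 8.5, Si 2.0 vs 0.19, SO4 0.85 vs 0.62, NO3 0.32
  vs 0.36, OC 0.65 vs 0.61, EC 0.036 vs 0.12 µg/m³); dust-day geometric
  SDs (1.15 mass, 1.25–1.3 species) are deliberately tighter than the
  published day-to-day spread so the default configuration is *cleanly
  separable* by the default classifier — the classifier-fidelity tests
  (sensitivity = specificity = 1) are statements about this synthetic
  regime, not about real filters, where boundary cases are expected.
* **Geography**: sites on a widely separated line; each ringed by ZIPs
  at 5–75 km so both sides of the 50 km (and 15 km) buffer are always
  exercised. No real geography is sampled.
* **Meteorology/co-pollutants**: seasonal sinusoid + Gaussian noise per
  ZIP-day, no missingness, no spatial correlation between ZIPs.
* **Visits**: ZIP-day counts are Poisson with log-mean
  `log(baseline) + beta_true · dust(site, date − lag_true) + day-of-week
  + holiday + seasonal sinusoid`, exploded to patient rows with ICD
  codes drawn era-appropriately from a small condition pool. Visit rates
  deliberately do *not* depend on temperature, so the meteorology terms
  act as correctly-specified nuisance covariates; patient identifiers
  are never reused and repeat visits by one person are not modelled
  (treated as independent, as the data source cannot distinguish them).

Passing recovery tests therefore demonstrate that the chain estimates
what it claims under the design's own assumptions (correct linkage,
shared site-level exposure, no unmeasured time-varying confounding).
They do not demonstrate robustness to exposure misclassification,
spatially heterogeneous exposure within the buffer, or overdispersed
counts — all real-data features outside the generator.

All generators draw from substreams derived from a single seed
(`seed + fixed stage offset`), so any stream is reproducible alone or
jointly; equal seeds give bit-identical outputs.

# Validation scale and reproduction

The validation suites run at sizes chosen to make Monte-Carlo error
small relative to the assertions: parameter recovery uses 100 seeded
replicates of 2 sites × 6 years with a planted odds ratio of 1.5 at
lag 2 (|β̂ − β| < 3·SE in ≥95 replicates; lag-profile maximum at lag 2
in ≥90), and null coverage uses 100 replicates of 2 sites × 3 years
(93–97 of 100 intervals covering OR = 1). `scripts/acceptance.R`
re-runs the chain from scratch at any seed and writes the recomputed
quantities as JSON.

# Known limitations

* ZIP discs, not polygons; population-weighted centroids are not
  supported. The disc radius is an effective scale, so "distance to the
  farthest boundary" semantics of true polygons are not reproduced.
* The classifier thresholds are calibrated defaults, not the (non-public)
  constants of the original algorithm; on real data they should be tuned
  against known events before use.
* No distributed-lag or moving-average exposures: with 1-in-3/1-in-6
  sampling, consecutive-day exposure histories are unobservable by
  design.
* Exact conditional inference (permutation) is not implemented; with
  set sizes ≤ 4 and one case per set the exact and partial-likelihood
  formulations coincide, which is what the cross-check relies on.
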