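---
title: "Simulating SDD surveillance strategies: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating SDD surveillance strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sddsurv)
```

## The experiment

Selective Digestive Decontamination (SDD) is accompanied, in most Dutch
ICUs, by admission cultures of throat, rectum and sputum followed by
surveillance cultures of the same three sites every Monday and Thursday.
`sddsurv` replays a cohort's complete culture history under reduced
surveillance intensities and quantifies what would have been lost: the
package's unit of comparison is a *scenario*, a deterministic subset of the
cohort's cultures.

* Scenario **A** keeps everything (the reference).
* Scenario **B** removes, for each admission, all surveillance cultures on
  one of the two protocol weekdays, chosen uniformly at random per
  admission and fixed for the whole stay.
* Scenario **C** removes all surveillance cultures.

Admission cultures and clinical (on-indication) cultures are always
retained, so the culture sets are nested: C ⊆ B ⊆ A. Every admission is an
independent analysis unit; readmissions of one patient are separate
admissions.

Two design points deserve explicit justification:

* **"Per patient" weekday removal is implemented per admission.** The
  analysis treats each ICU admission separately throughout, so the
  once-weekly draw is fixed per admission; a readmitted patient may draw a
  different weekday on a later stay. A per-week redraw would break the
  nesting guarantee within an admission and model a different (rotating)
  protocol.
* **The draw is a seeded hash of the admission id**
  (`assign_dropped_weekday()`), not a sequential RNG, so scenario
  construction is independent of table ordering and reproducible from the
  master seed alone. Surveillance cultures falling on weekdays other than
  Monday/Thursday — possible in real exports — are retained in B, because
  the removal rule is defined only on the two protocol days.

## New findings and the dedup rules

The primary outcome counts *organisms*, not samples. Isolates are collapsed
into **new findings** — (species, susceptibility profile) combinations not
previously cultured during the same ICU stay — by a chronological sweep per
admission:

1. An isolate opens a new finding unless an earlier (or same-day,
   already-attributed) isolate of the same species has a *non-differing*
   profile.
2. Two profiles differ only if they disagree on an agent tested in **both**
   panels (`profiles_differ()`). Agents tested in only one panel are
   ignored: laboratories vary panel composition, and requiring shared-agent
   disagreement prevents panel differences from manufacturing "new"
   organisms. The cost of this choice is mild non-transitivity (an empty
   panel differs from nothing); the sweep resolves it by comparing each
   isolate against the already-accepted findings in order.
3. Intermediate (I) results count as different from both S and R when
   comparing profiles — conservative for resistance detection.
4. Same-day duplicates (multiple sites, or surveillance + clinical on one
   day) collapse to a single finding. If any same-day source is clinical,
   the finding is attributed to the clinical culture and the SDD culture is
   regarded as non-informative that day.
5. Cultures taken before ICU admission are never consulted.

Clinical relevance is assigned per finding at three mutually exclusive
levels with precedence **direct** (MDRO: MRSA, VRE, ESBL producers, …) >
**high** (resistant to third-generation cephalosporins or fluconazole,
intrinsic or acquired) > **infection-related** (adjudicated causative
pathogen of an ICU-acquired infection). The flags behind these levels are
inputs: the package performs no genotypic inference.

## Intensification triggers

Persistent or recurrent colonisation detected after ≥ 4 days of SDD
application indicates protocolised intensification (eight-times-daily
topical dosing and/or nebulised antibiotics). `detect_triggers()`
implements this as a configurable rule table: by default any topically
targeted organism class (aerobic Gram-negatives, *S. aureus*, yeasts) at
any SDD site with `min_sdd_day = 4`. Choices made where the protocol
leaves room:

* **Day anchor.** The SDD clock anchors at the calendar date of the first
  topical administration (day 0), so "after ≥ 4 days" means day index ≥ 4;
  a stricter day-1 anchor is a one-line change via the rule table's
  `min_sdd_day`.
* **Event granularity.** One event per admission × organism class × day:
  same-day detections at several sites do not multiply triggers, mirroring
  the finding-level dedup. Recurrent colonisation (clear, then
  re-colonised) triggers again on a later day; the rules do not
  distinguish persistence from recurrence.
* Both SDD and clinical cultures are eligible — in practice most triggers
  come from surveillance samples, but a clinical sputum culture can reveal
  persistence equally well. Adherence to triggered intensification (how
  often clinicians actually escalate) is an input for discussion, not
  simulated behaviour.

## Rates, bootstrap, and rounding

All detection outcomes are reported per 1,000 ICU days with the summed
fractional length of stay of all analysed admissions as the denominator;
admission-level fractions are never rounded before summing. Confidence
intervals come from a **percentile bootstrap** with the admission as the
resampling unit: replicates resample admissions with replacement, keeping
each admission's events and days together, and recompute the cohort ratio;
the CI is the 2.5th/97.5th percentile of 1,000 replicates. Percentile
rather than BCa is the simplest defensible reading of "bootstrapping" for
a ratio estimator at this cohort size; the admission is the unit because
events within a stay are strongly dependent. Degenerate replicates with a
zero day-denominator are redrawn.

Numerical conventions, applied uniformly: quantiles (IQRs and bootstrap
percentiles) use the median-unbiased estimator (`quantile(type = 8)`);
reported integers and percentages are rounded half away from zero
(`round_half_up()`), once, at the reporting layer; all intermediate
arithmetic is exact. Day arithmetic uses whole calendar days (cultures
carry dates, not timestamps) because the protocol reasons in days and
weekday schedules.

## Costing

Only SDD cultures enter cost analyses. A culture's cost is the exact sum
of order fee, plate expenses, species-identification and
susceptibility-testing costs. Missing cost records (a distinguished
marker, never zero) are imputed with the median total of non-missing SDD
cultures in the same positivity stratum (positive vs negative), pooled
across categories and sites; imputation preserves stratum medians by
construction and touches only missing records. Cost per relevant finding
divides the scenario's total SDD culture cost by the count of relevant
findings detected in SDD cultures; with zero relevant findings it is
undefined (NA), not infinite. Per-admission summaries include every costed
admission present in the scenario, including those left without SDD
cultures by the filter. Inputs are assumed to be at a single price level;
no inflation indexing is performed.

## The synthetic cohort generator

`generate_cohort()` exists so that every downstream stage is testable
without patient-level data. It emulates, per admission:

* **Length of stay**: lognormal, `meanlog = 1.609`, `sdlog = 1.133`
  (median 5.0 days, quartiles ≈ 2.3 and 10.7), truncated below at 0.3
  days. Admission dates are uniform over a one-year window, so
  Monday/Thursday schedules vary realistically across admissions.
* **Colonisation**: independent two-state daily Markov chains per organism
  class (Gram-negative aerobes, *S. aureus*, yeasts, other respiratory
  pathogens) — initial carriage with the class's admission prevalence,
  carried→clear with a daily clearance probability reflecting
  decontamination, clear→carried with a small daily acquisition
  probability. Each carriage episode draws a fresh species, susceptibility
  profile and relevance label, so repeated detections of one episode agree
  in species, profile and relevance — the outcome counts organisms, and a
  class-level state space keeps the model small while matching the
  topical-targeting logic.
* **Cultures**: day-0 admission set (three sites), full three-site
  surveillance sets on every Monday/Thursday from day 1, and clinical
  cultures as a daily Poisson stream (default 0.68/day, site sputum or
  other). Isolates are sampled from the carriage state through per-site
  sensitivities.
* **Costs**: fixed tariffs — EUR 30 order fee + EUR 24 plates per culture,
  EUR 14 identification per isolate, EUR 66 susceptibility testing per
  bacterial isolate (yeasts are identified but not routinely AST-tested).
  This reproduces the characteristic cost ladder: EUR 54 for a negative
  culture, EUR 68 for a yeast-only positive, EUR 134+ for bacterial
  positives — and makes positive cultures costlier than negatives, as in
  real tariff data. 0.2% of cost records are set missing.
* **Reproducibility**: every admission draws from a substream seeded by a
  hash of (master seed, admission id), so cohorts are byte-identical across
  runs and invariant to simulation order.

The defaults were calibrated once, by moment matching on cohorts of 2,000
admissions, to the marginals a large mixed ICU cohort under SDD exhibits:
admission-culture positivity ≈ 62%, surveillance ≈ 38%, clinical ≈ 26%,
≈ 87% of admissions with at least one positive admission culture, and
≈ 9.9% of new findings clinically relevant (split ≈ 10:76:14 across
direct/high/infection-related). Clearance and acquisition rates are
calibration knobs, not epidemiological estimates: the available marginals
do not identify the acquisition-versus-persistence split, only constrain
their combination.

**What the generator does not model** — and hence what passing tests do
not establish about real data: between-patient transmission, antibiotic
pharmacodynamics, site-specific species niches beyond the sensitivity
matrix, panel heterogeneity across years, clinical-culture clustering
around deterioration, correlation between length of stay and colonisation
pressure, and any feedback from culture results to clinical behaviour
(stopping rules, extra diagnostics). Scenario comparisons on synthetic
cohorts validate the *machinery* — nesting, dedup, delay accounting,
bootstrap coverage, cost aggregation — not the clinical magnitudes, which
depend on the cohort being analysed.

## Degenerate inputs and edge behaviour

Validation (`validate_cohort()`) reports violations as data rather than
raising, so partially dirty exports can be triaged; loading
(`load_cohort()`) fails fast on schema, date-parse and referential errors.
Cultures before SDD start produce negative SDD-day indices and never
trigger. Admissions without an SDD start time are skipped by trigger
detection with a warning. An empty isolate table is a valid all-negative
cohort. Imputation refuses a stratum that has missing values but no donor
records.

## Problem sizes

The shipped test-suite and the acceptance script exercise the pipeline at
sizes chosen to make the statistical checks sharp while keeping runs
convenient: calibration-recovery at 2,000 admissions; bootstrap coverage on
200 simulated cohorts of 500 admissions with 1,000 bootstrap iterations
each; nesting and oracle-equivalence properties on hundreds of small random
cohorts. Larger cohorts change nothing structurally — generation and
analysis scale linearly in admissions.
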