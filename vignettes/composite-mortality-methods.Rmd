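---
title: "Methods: composite mortality endpoints and their validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composite mortality endpoints and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mortcomp)
```

## Overview

`mortcomp` models the construction and quality assessment of a composite
per-patient death date assembled from several imperfect mortality sources,
benchmarked against a near-complete death index. This vignette documents the
statistical model, the parameter choices and their rationale, the numerical
decisions, and the limits of what the synthetic experiments demonstrate.

## The composite model

Each source $k$ contributes at most one assertion $(k, d_k)$ per patient.
The resolved date is

* the date asserted by two or more sources, when one exists (agreement
  beats everything and is independent of source ordering);
* otherwise the date of the highest-priority asserting source, with priority
  SSDI > CDD1 > EHR. SSDI sits on top because public death-index dates track
  the gold standard more closely than clinic-entered fields; the EHR field
  is last because it is typed by hand during clinical care.

Two defensive rules are fixed here because the three-source case never
exercises them: if two *different* dates are each supported by the same
number of sources, the hierarchy decides between them (relevant only with
four or more resolving sources); duplicate assertions within one source are
collapsed to that source's earliest date before resolution.

Chart abstraction (ABS) is deliberately excluded from conflict resolution.
Abstraction is commissioned only for patients with no date in any other
source, so it can only fill gaps; letting it override other sources would
misrepresent the data-generating process. Fill eligibility additionally
requires no recorded activity within `recency_days` (default 60 days) of the
reference date — a recently active patient is presumed alive.

A composite date strictly before the patient's advanced-diagnosis date is a
known error mode (mistyped years, mislinked records) and is removed; the
boundary case (death on the diagnosis date) is retained. In the stepwise
builds the final version applies abstraction fill *before* the plausibility
filter, so an abstracted date is subject to the same error screening; the
benchmark is computed post-filter throughout.

Vital status is derived purely from date presence. The model therefore has
no "dead, date unknown" state — a real limitation of composite endpoints
that collapse status and date into one variable.

## Linkage

External sources and the gold index carry only identifiers (first and last
name, birth date, state). Matching is deterministic and multi-pass, from
strict to lenient: (1) exact last name, first name, birth date; (2) exact
last name and birth date with the first name within Levenshtein distance 1;
(3) exact names and state with the birth date off by a day/month field swap.
The first pass that identifies exactly one patient wins; a pass that yields
two or more candidates leaves the record finally unmatched. Unmatched beats
guessed: a wrong link manufactures a false positive *and* hides a true
death, whereas a missed link only loses sensitivity. Name comparison is
case-insensitive and whitespace-trimmed.

Gold records carry a match-quality annotation as data rather than a
recomputed linkage score, because the internal scoring of a national death
index is not reproducible from outside. The conservative classification —
`exact` and `probable` matches are deaths; `likely_false`, `unclassifiable`
and absent records are alive — errs toward calling patients alive, which
deflates measured PPV rather than sensitivity.

## Validation metrics

From the 2×2 table (A, B, C, D) the four standard accuracy metrics are
computed with Wald intervals $p \pm z_{0.975}\sqrt{p(1-p)/m}$ truncated to
$[0,1]$, $m$ being each metric's own denominator. Wald (not exact) intervals
are the default because published benchmark intervals for this design are
Wald-consistent at these sample sizes; Clopper–Pearson is available via
`ci_method = "clopper-pearson"`. A metric with zero denominator is reported
as `NA`, never 0.

Date agreement at window $w \in \{0, 15, 30\}$ days uses the composite
deaths $A+B$ as denominator: the windowed-agreement numerator only ever
contains patients with a composite date, and composite-only deaths (no gold
death) are counted as disagreements. This makes the three windows nested by
construction ($w=0 \subseteq w=15 \subseteq w=30$) and comparable across
dataset versions. Window comparison is inclusive ($|\Delta| \le w$).

Per-practice sensitivity is restricted to practices with at least
`min_patients` (default 100) patients, because a practice with three deaths
can only have sensitivity 0, 1/3, 2/3 or 1. Boxplot hinges use type-7
(linear-interpolation) quantiles — R's default — with whiskers at the most
extreme observations within 1.5 IQR of the hinges.

## Contingency reconstruction

Published benchmark tables print rounded metrics but not the underlying
counts. `reconstruct_contingency()` inverts the rounding: given specificity,
PPV, NPV (each within half a printed unit of the true ratio) and $n$, it
enumerates integer tables and returns the one minimising the summed absolute
metric deviation. The search is exact yet fast because each constraint
confines its cell to a narrow band: for every false-positive count $B$, the
PPV band admits only $A \in [B\frac{p-t}{1-p+t},\ B\frac{p+t}{1-p-t}]$, and
the NPV band then pins $D$ to within a few integers. The per-metric bound
`tol` defaults to $2\times10^{-4}$ — double the worst-case rounding error of
values printed to two decimals in percent — and candidates must also keep
the *summed* deviation below `3 * tol`. Ties are broken by smallest $B$,
then $C$, then $D$, making degenerate cases (undefined input metrics passed
as `NA`) deterministic. Inputs admitting no table within tolerance raise a
`mortcomp_infeasible` error rather than returning a least-bad guess.

## Survival comparison

Kaplan–Meier estimation is delegated to `survival::survfit()` (product-limit
with events-first handling of ties); the package's contribution is the input
convention and the comparison. Composite-based curves censor patients
without a date at `min(last_activity_date, cutoff)` — the standard EHR
convention, and the one that interacts correctly with simulated loss to
follow-up. The gold-based curve censors at the study cutoff, since the gold
index is treated as complete through that date. Time is measured in days
from advanced diagnosis (months = days/30.4375 for display). The mechanism
the comparison demonstrates is exact, not stochastic: recoding any death as
a censoring at the same time can only increase $\hat S(t)$ pointwise, so
missed deaths always inflate survival; `compare_curves()` reports survival
at chosen horizons and the largest horizon-wise excess over the gold curve.
Medians are reported as `NA` when the curve never reaches 0.5.

## The synthetic study and its calibration

The simulator emulates a multi-tumor advanced-cancer cohort observed through
a fixed cutoff (2015-12-31, matching gold-standard availability):

* **Cohort.** Tumor mix proportional to the published cohort sizes
  (advNSCLC : advMelanoma : mCRC : mBC = 10195 : 1622 : 7325 : 3792).
  Enrollment uniform over 2011–2015 for advNSCLC and 2013–2015 otherwise —
  accrual patterns are not reported, and uniform is the neutral choice.
  Survival is exponential from diagnosis (configurable Weibull shape) with
  tumor medians 12 / 20 / 28 / 36 months: the benchmarks state only that the
  tumor types span short versus long survival, so medians were fixed once at
  values typical of advanced NSCLC through metastatic breast cancer in this
  era. Deaths after the cutoff are unobservable and stored as missing.
* **Sources.** Each true death is captured independently per source. Capture
  probabilities are calibrated so the stepwise union sensitivities reproduce
  the published progression 0.66 → 0.84 → 0.89 → 0.91 (EHR 0.66, CDD1
  $1-\frac{0.16}{0.34}\approx0.53$, SSDI $1-\frac{0.11}{0.16}=0.3125$, ABS
  $1-\frac{0.09}{0.11}\approx0.18$ among remaining gaps). Captured dates are
  exact with per-source probability (EHR 0.89, CDD1 0.93, SSDI 0.97, ABS
  0.95, mirroring each source's published exact-agreement level), otherwise
  perturbed by a rounded Gaussian offset (sd 7 days) or, with probability
  0.005, a ±365-day year typo — the error mode actually observed in EHR
  death fields. Alive patients acquire spurious records at rate 0.001 per
  source. External-source identifiers are corrupted per field at rate 0.01
  (single-character name edits, day/month swaps, state changes).
* **Practice heterogeneity.** Per-practice EHR capture is Beta-distributed
  with mean 0.66 and concentration 12, putting the 25th percentile near
  0.57 — the reported lower quartile of practice-level completeness. Forty
  practices with lognormal size weights give a realistic size spread.
* **Gold index.** Capture 0.99 with exact dates; match-quality classes for
  true deaths drawn as exact 0.88 / probable 0.10 / unclassifiable 0.02, and
  35% of alive patients carrying a `likely_false` record, chosen to emulate
  the published cohort-level class split (about 28% no record, 46% exact, 6%
  probable, 17% likely false, 3% unclassifiable).

One integer seed determines everything; per-stage seeds are derived as
`(seed %% 1e6) * 1009 + offset`, keeping them within 32-bit range.

**What the simulator does not model:** cause of death, informative
censoring (loss to follow-up is independent of survival), source-to-source
correlation in capture (a patient in hospice is likely missed by *all*
sources), calendar drift in source quality, duplicate patients, and
real identifier distributions (names come from a synthetic syllable
inventory). Passing tests therefore demonstrate correctness of the
*machinery* — linkage, resolution, metrics, survival mechanics — under a
plausible error structure, not the field performance of any real source.

## Test problem sizes

The suite favours closed-form and hand-enumerable fixtures; stochastic
checks use the smallest sizes at which 3-standard-error bands are
informative: 10,000 patients for the calibrated stepwise-sensitivity check
(binomial bands around the four targets, specificity drift under 2
percentage points), 5,000 for exhaustive linkage recovery at zero
corruption, 100 × 150 patients for date-agreement nesting across random
configurations, and 50 × 200 for the censoring-dominance property. The
calibrated check pins the per-source capture probabilities, so practice
heterogeneity is disabled there (it is exercised by the per-practice tests);
linkage and gold corruption are likewise zero so that measured sensitivity
estimates capture alone.

## Known limitations

* Agreement between two *wrong* dates wins over a correct hierarchy date by
  design; with independent per-source errors this is vanishingly rare, but
  correlated upstream errors (a shared bad feed) would defeat it.
* The reconstruction oracle assumes the published metrics were computed from
  one table with the stated $n$; inconsistent or re-rounded inputs surface
  as infeasibility, not as a warning with a best guess.
* Wald intervals undercover for denominators below roughly 40; use the
  Clopper–Pearson option for small strata.
* The matcher is deterministic by scope: no probabilistic (Fellegi–Sunter)
  weighting, no SSN handling, and ambiguity always loses the record.
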