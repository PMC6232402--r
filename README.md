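# mortcomp

Composite real-world mortality endpoints: construction, record linkage, and
validation against a gold-standard death index.

## The problem

Survival endpoints computed from electronic health records (EHRs) are only as
good as the mortality data behind them. In routine oncology care nobody is
paid to record that a patient died: patients transfer, enter hospice, or move
away, and their deaths never reach the structured "date of death" field. A
missed death does not disappear from the analysis — it silently becomes a
censored observation, so Kaplan–Meier curves drift upward and treatments look
better than they are.

`mortcomp` implements the standard remedy as a tested, reusable pipeline: a
**composite mortality variable** amalgamated from several imperfect sources —
structured EHR fields, a commercial death dataset (CDD1), the Social Security
Death Index (SSDI), and targeted chart abstraction (ABS) — each linked to the
cohort by deterministic identifier matching, merged under agreement and
source-hierarchy rules, and benchmarked at every step against a near-complete
national death index treated as the gold standard.

The package is aimed at real-world-evidence methodologists and biostatisticians
who need to (a) build such a composite from their own source tables, (b)
quantify its quality, and (c) demonstrate what incomplete capture does to
downstream survival estimates. Because real mortality sources are proprietary,
the package ships a seeded synthetic multi-source simulator with the relevant
error structure, so every stage is testable end to end.

## The method

For each patient, sources assert candidate death dates. Resolution follows
two rules:

1. **Agreement** — if two or more sources assert the same date, that date is
   used;
2. **Hierarchy** — if all asserted dates conflict, SSDI is preferred (most
   reliable against the gold standard), then CDD1, then EHR.

Chart-abstracted dates never participate in conflict resolution; they only
fill gaps for patients with no date elsewhere and no activity in the previous
60 days. Death dates before the advanced-diagnosis date are removed as known
errors. Vital status is simply "dead iff the composite date is populated".

Each stepwise dataset version *v* is benchmarked against the gold standard
through the 2×2 table (A = death in both, B = composite only, C = gold only,
D = neither):

    sensitivity = A/(A+C)    specificity = D/(B+D)
    PPV         = A/(A+B)    NPV         = D/(C+D)

with Wald 95% intervals p ± 1.96·√(p(1−p)/m), plus date agreement at exact,
±15-day and ±30-day windows (composite-only deaths count as disagreements;
the denominator is all composite deaths A+B). Per-practice sensitivity
(practices with ≥100 patients) summarises capture heterogeneity, and
Kaplan–Meier curves per version against the gold-based curve quantify
survival overestimation.

A companion oracle, `reconstruct_contingency()`, inverts rounded published
metric rows: given specificity, PPV, NPV and n it recovers the integer 2×2
table by bounded exact search, so unpublished cells (e.g. a row's
sensitivity) can be recomputed from what a paper prints.

## Worked example

```r
library(mortcomp)
library(dplyr)

cfg    <- sim_config(n_patients = 2000, seed = 42)
study  <- simulate_study(cfg)                    # cohort + 4 sources + gold
linked <- link_study(study)                      # identifier matching + calls
versions <- build_dataset_versions(study$cohort, linked$assertions,
                                   reference_date = cfg$study_cutoff)
benchmark_versions(versions, linked$calls) %>%
  select(version, n, sensitivity, specificity, ppv, npv, date_agreement_exact)
#>   version               n sensitivity specificity   ppv   npv date_agreement_exact
#> 1 EHR_only           2000       0.648       0.980 0.967 0.755                0.843
#> 2 SSDI_only          2000       0.327       0.990 0.969 0.620                0.938
#> 3 EHR_CDD1           2000       0.832       0.969 0.960 0.865                0.876
#> 4 EHR_CDD1_SSDI      2000       0.883       0.968 0.961 0.902                0.902
#> 5 EHR_CDD1_SSDI_ABS  2000       0.902       0.968 0.962 0.916                0.903
```

Sensitivity climbs from 65% (structured EHR alone) to 90% in the final
composite while specificity stays within about one percentage point — each
added source fills deaths the others missed without inventing many new ones.
A single version can be inspected in detail:

```r
final <- versions %>% filter(version == "EHR_CDD1_SSDI_ABS")
validation_report(final, linked$calls, label = "final composite")
#> <mort_validation> final composite (n = 2000; A=855 B=34 C=93 D=1018)
#>   sensitivity   90.19% (88.30%, 92.08%)
#>   specificity   96.77% (95.70%, 97.84%)
#>   ppv           96.18% (94.91%, 97.44%)
#>   npv           91.63% (90.00%, 93.26%)
#>   date agreement (+/-0 d): 90.33%
#>   date agreement (+/-15 d): 95.39%
#>   date agreement (+/-30 d): 95.61%
```

The survival impact of incomplete capture (missed deaths masquerade as
censorings):

```r
km_final <- km_estimate(survival_input(final, study$cohort, cfg$study_cutoff))
km_ehr   <- km_estimate(survival_input(versions %>% filter(version == "EHR_only"),
                                       study$cohort, cfg$study_cutoff))
km_gold  <- km_estimate(survival_input(
  linked$calls %>% transmute(patient_id, death_date = gold_death_date),
  study$cohort, cfg$study_cutoff, censor = "cutoff"))
compare_curves(list(EHR_only = km_ehr, final = km_final), km_gold,
               horizons = c(365, 730))
#>   version  median_days surv_365d surv_730d max_overestimate
#> 1 EHR_only         853     0.751     0.559           0.112
#> 2 final            624     0.665     0.452           0.0104
```

The EHR-only dataset overstates one-year survival by 11 percentage points and
inflates median survival by more than seven months; the full composite is
within one point of the gold-standard curve. `plot_km_curves()` and
`plot_practice_sensitivity()` draw the corresponding figures.

The whole pipeline — simulate, link, compose, benchmark, survive, with CSV
outputs and a JSON manifest — runs as one call (`run_pipeline(cfg, "out/")`)
or from the shell via `inst/cli/mortpipe.R`.

## Output schemas

| file | columns |
|---|---|
| `cohort.csv` | patient_id, first/last name, birth_date, state, practice_id, tumor_type, advanced_diagnosis_date, last_activity_date, true_death_date |
| `source_<id>.csv` | record_id, source_id, patient_id (internal sources), identifiers, death_date |
| `gold.csv` | record_id, identifiers, death_date, match_quality |
| `match_audit.csv` | source_id, record_id, patient_id, match_pass, score |
| `vital_status.csv` | patient_id, status, reason, gold_death_date |
| `composite_<version>.csv` | version, patient_id, death_date, contributing_sources, resolution |
| `report.csv` | version, n, A–D, four metrics with `.low`/`.high`, date agreement columns |
| `km_<version>.csv` | time, n_risk, n_event, n_censor, surv |
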