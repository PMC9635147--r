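# asthmasteps

Derive asthma treatment steps — a proxy for asthma severity — from electronic
prescription records.

Asthma guidelines (BTS/SIGN) organise pharmacotherapy into stepwise levels:
reliever-only use at the bottom, low-dose inhaled corticosteroid (ICS) above
it, then add-on controllers and rising ICS doses up to high-intensity
treatment. The step a patient is being treated at is therefore a readable
severity proxy — but prescription databases record none of it directly. They
hold free-text medication names ("Clenil Modulite 100mcg inhaler"), free-text
dose directions ("TAKE TWO PUFFS TWICE DAILY", "2 PUFS BD"), and dates.

`asthmasteps` turns those raw records into step trajectories:

1. **Identify** asthma medications from free-text names against an editable
   catalogue (generic + brand substrings), and exclude non-asthma records
   (nasal/dermatological preparations, deletion notes, out-of-period rows)
   with a fully accounted attrition report.
2. **Extract** dose frequency, dose quantity and unit strength from the
   free-text directions with rule-based parsers (including the "PUFS" typo
   rule and suffix-safe microgram/milligram value matching), and **impute**
   missing components by the per-medication mode.
3. **Band** each prescribed daily ICS dose into LOW / MEDIUM / HIGH / UNKNOWN
   on the medication's own guideline thresholds.
4. **Assemble regimens** over a 120-day lookback window at every prescription
   event (ICS band + add-on controller classes; SABA is a reliever, never an
   add-on) and **classify** each regimen to treatment step 0–4 via a
   configurable, provably total decision tree.
5. **Summarise trajectories**: step episodes with censoring-aware durations,
   step-up/step-down transition matrices, and person-year summaries.
6. **Simulate**: a synthetic prescription-record generator with known
   ground-truth trajectories, so the whole pipeline is testable end to end
   without access to restricted health data.

## Worked example

```r
library(asthmasteps)
library(tibble)

rx <- tribble(
  ~patient_id, ~prescribed_date, ~medication_name, ~formulation, ~dose_text,
  "P1", "2009-02-10", "CLENIL MODULITE 100MCG INHALER", "MDI", "TAKE TWO PUFFS TWICE DAILY",
  "P1", "2009-03-12", "CLENIL MODULITE 100MCG INHALER", "MDI", "TAKE TWO PUFFS TWICE DAILY",
  "P1", "2009-06-20", "CLENIL MODULITE 100MCG INHALER", "MDI", "2 PUFS BD",
  "P1", "2009-07-18", "SERETIDE 250/25 EVOHALER",       "MDI", "ONE TO BE TAKEN TWICE DAILY",
  "P1", "2009-08-15", "SERETIDE 250/25 EVOHALER",       "MDI", "ONE TO BE TAKEN TWICE DAILY",
  "P1", "2009-08-15", "VENTOLIN 100MCG INHALER",        "MDI", "TAKE 2 PUFFS AS REQUIRED",
  "P2", "2009-06-01", "AMOXICILLIN 500MG CAPSULES",     "CAP", "ONE THREE TIMES DAILY",
  "P2", "2009-07-01", "VENTOLIN 100MCG INHALER",        "MDI", "TAKE 2 PUFFS AS REQUIRED")

res <- run_pipeline(rx, study_start = "2009-01-31", study_end = "2009-12-31")
res$events
#> # A tibble: 4 × 7
#>   patient_id event_date ics_band addons saba_only regimen                   step
#>   <chr>      <date>     <chr>    <chr>  <lgl>     <chr>                    <int>
#> 1 P1         2009-06-20 LOW      ""     FALSE     Low-strength ICS             1
#> 2 P1         2009-07-18 MEDIUM   "LABA" FALSE     Medium-strength ICS + L…     3
#> 3 P1         2009-08-15 MEDIUM   "LABA" FALSE     Medium-strength ICS + L…     3
#> 4 P2         2009-07-01 NONE     ""     TRUE      SABA                         0
```

Patient P1's beclometasone at 2 puffs × 2/day × 100 µg = 400 µg/day bands LOW
(Step 1); the switch to a combination inhaler (250 µg fluticasone twice daily
= 500 µg/day, MEDIUM, plus its LABA component) takes them to Step 3. The
amoxicillin row is excluded as `NO_MATCH`, P2's salbutamol-only use is Step 0,
and both patients' pre-run-in events (the first 120 study days) are dropped.
Every input row is accounted for:

```r
res$report$total_input                      # 8
res$report$excluded$NO_MATCH                # 1
res$report$retained                         # 7
# invariant: total_input = retained + sum(excluded) + quarantined
```

Trajectory summaries come from the same result object: `res$episodes`
(durations until step change, final episodes censored), `res$durations`
(medians/IQRs overall, by direction, by step), `res$transitions` (transition
matrix and single-step-move fractions), `res$person_years`, `res$band_mix`.

### Synthetic cohorts with ground truth

```r
cfg <- simulation_config(n_patients = 500, seed = 1, text_noise = noise_off())
sim <- simulate_cohort(cfg)
res <- run_pipeline(sim$prescriptions, study_start = cfg$study_start,
                    study_end = cfg$study_end)
merged <- merge(res$events, sim$truth$events)
mean(merged$step == merged$true_step)       # 1 — exact recovery at zero noise
```

## Command line

A thin CLI wraps simulation and the pipeline:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "asthmasteps.R", package = "asthmasteps"))')
Rscript $CLI simulate --n 100 --seed 1 --out rx.csv --truth truth.csv
Rscript $CLI run --input rx.csv --study-start 2009-01-31 --out-dir results/
```

## Configuration is data

The medication catalogue (brands, licensed strengths, dose-band thresholds),
exclusion keywords, frequency keywords, and the step decision trees (adult
and paediatric) ship as editable CSVs under `inst/extdata/`; each loader
validates its file (the step tree must cover every band × add-on
configuration, with exactly one Step-1 configuration) so local adaptations
fail loudly, not silently. See the vignette in `vignettes/` for the method
description and the reasoning behind the numerical choices.
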