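---
title: "Deriving asthma treatment steps from prescription records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving asthma treatment steps from prescription records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asthmasteps)
```

## The problem

Asthma severity is well proxied by the intensity of treatment a patient is
maintained on. Guidelines organise that intensity into steps: Step 0
(reliever only), Step 1 (low-dose inhaled corticosteroid, ICS), Step 2
(low-dose ICS plus one add-on controller), Step 3 (multiple add-ons or
medium-dose ICS), Step 4 (high-dose ICS or medium-dose with multiple
add-ons). Prescription databases never record the step; they record dated
free-text medication names and free-text dose directions. This package
derives the step, at every prescription event, by rules — no statistical
model is fitted, so every assignment is auditable back to a rule and a
record.

## Pipeline stages and their numerical choices

### 1. Medication identification and exclusions

Names are matched by upper-cased substring against a catalogue of generic
and brand names (`inst/extdata/medication_catalogue.csv`). Exactly one entry
may match; two matches indicate overlapping catalogue keys and raise an
error rather than a silent pick. Discontinued brands are separate rows
carrying the parent drug's banding thresholds.

Exclusions are applied in a fixed precedence so attrition counts are well
defined: out-of-period date, deletion-note keyword, no catalogue match,
spray/drop formulation (ICS entries only — those are nasal or
dermatological uses), non-asthma indication keyword, non-asthma brand.
Corticosteroid solutions (respules, sachets, nebuliser vials) are retained
but reclassified to `ORAL_OR_NEB_STEROID`: they are not inhaled ICS and
neither generate prescription events nor join regimens. Malformed rows
(missing date, patient or name) are quarantined to a reject table, never
dropped, and the attrition report satisfies
`total_input = retained + sum(excluded) + quarantined` as a hard assertion.

### 2. Free-text dose extraction

Three rule-based extractors, each a pure function of the text:

* **Frequency** (doses/day): a keyword table
  (`inst/extdata/frequency_keywords.csv` — TWICE, MORNING AND NIGHT, BD,
  TDS, NOCTE, …) scanned longest-phrase-first on word boundaries, so
  "MORNING AND NIGHT" wins over an embedded "ONCE".
* **Quantity** (puffs/dose): the numbers one–four (numerals or words),
  accepted only with a `TAKE`/`INHALE` prefix or a
  `DAILY`/`AT`/`TO BE TAKEN`/`PUF`/`P ` suffix. `PUF` (single f) is
  deliberate: it catches both "PUFFS" and the common "PUFS" typo. Numbers
  above four are never quantities.
* **Strength**: values are matched against the closed lists of unit
  strengths marketed in micrograms and milligrams, scanned in descending
  order with a `(?<![0-9.])` guard, so a value never matches as the suffix
  of a larger one ("250MCG" is 250, never 50; "0.5MG" is 500 µg, never
  5000). Combination ICS+LABA products use the `ICS/LABA` slash convention
  ("SERETIDE 250/25": ICS component before the slash). A unitless
  "SERETIDE 250" stays unparsed rather than guessed. Strength is taken from
  the dose directions first, falling back to the medication name.

Missing components are imputed by the **mode over all parsed records of the
same medication**; ties break to the smallest value (the conservative,
lower-dose reading). Imputation runs before licensed-strength validation,
so an imputed value faces the same exact-membership check as a parsed one;
strengths outside the licensed list are excluded as
`STRENGTH_OUT_OF_RANGE`. Observed values are never altered, and imputation
flags are kept per record.

### 3. Daily-dose banding

Daily dose = frequency × quantity × strength (µg/day), rounded half-up to
the microgram. Guideline tables give per-medication thresholds `low`,
`medium`, `high`; ranges are rule-forced: low is `(0, low]`, medium is
`[low+1, medium]` (or `[medium/2, medium]` when no low dose is
recommended), high is `[medium+1, 4×medium]` (or `[high/2, 2×high]` when no
medium is recommended), and anything above the high range is `UNKNOWN` —
off-table, treated as at-least-high downstream. Classification is
implemented as a **sequential upper-bound scan** (≤ low upper → LOW,
≤ medium upper → MEDIUM, ≤ high upper → HIGH, else UNKNOWN): any gap
between printed ranges is absorbed by the next band up, which makes the
classifier provably total and monotone in dose. Both properties are
property-tested over 1,000 random threshold triples.

### 4. Regimens over a 120-day lookback window

At each prescription event (one per patient-day with at least one asthma
prescription) the regimen is read off the 120-day window ending on, and
including, the event date: 120 days is the upper bound of UK repeat
prescription durations, so one window covers one refill cycle. The ICS band
is computed per ICS-containing product from that product's **most recent**
daily dose in the window, each on its own thresholds, and the regimen takes
the **maximum** band across products (UNKNOWN dominating, as it denotes a
dose above the high range). Add-ons are the non-ICS controller classes
present in the window; combination inhalers contribute their LABA
component. SABA is a reliever — never an add-on; it only marks the
SABA-only (Step 0) regimen when nothing else is in the window. Events in
the first 120 study days are discarded (run-in): staggered refills are
still accumulating there and windows under-cover the regimen.

A side effect of the window arithmetic: a 120-dose canister prescribed at
two puffs twice daily lasts 30 days at full use, so a single refill keeps a
patient "on" ICS for the whole window down to 25% usage
(`continuation_capture_fraction()`), a deliberate leniency of the method.

### 5. Step classification

The decision tree is data (`inst/extdata/step_rules_adult.csv`): ordered
rules over ICS band × add-on count, first match wins. The loader proves two
properties at load time, over all 5 bands × 2⁴ add-on subsets: **totality**
(every configuration reaches a step) and **Step-1 uniqueness** (exactly one
configuration — low-dose ICS with no add-ons — classifies to Step 1).
A paediatric variant ships alongside; swapping trees is a file path.

### 6. Trajectory statistics

Steps are observable only at prescription events, so an episode (a maximal
run of same-step events) lasts from its first event to the **first event of
the next episode** — the step change is only seen when the new prescription
appears. The final episode of each patient has no observed change: it is
censored, excluded from duration summaries, and the censored percentage is
disclosed per stratum. Transition matrices count observed step changes;
the diagonal carries within-step regimen switches; transitions touching
Step 0 can be excluded (the pipeline default), since lapses into
reliever-only use often reflect non-adherence rather than sanctioned
de-escalation. Person-years are 365-day blocks anchored at each patient's
first event — anchoring at a calendar date would split follow-up
arbitrarily — and blocks without any event are excluded from denominators.

## The synthetic cohort and its ground truth

Real datasets of this kind are access-controlled, so the package ships a
generator (`simulate_cohort()`) whose records have the structure the parser
must face: ~30-day jittered refills, brand or generic names with embedded
strength tokens, six direction phrasings, Latin abbreviations, the "PUFS"
typo, and tunable missingness of frequency/quantity/strength. Its defaults
are the study conditions; `noise_off()` zeroes only the text degradation.

The latent process changes step only at review (refill) times. On entering
a step the **direction of the next change is drawn first**, then the dwell
time from a geometric distribution over 30-day cycles whose mean depends on
the direction (defaults 130 days before a step up, 300 before a step down).
Drawing direction first is what encodes the clinical asymmetry — with
competing memoryless clocks, dwell time would be independent of direction
and the asymmetry unrecoverable.

Ground truth is defined **window-wise**: for every prescription day the
true step is computed from the true component classes and bands under the
same 120-day window convention, using none of the text parsing, dose
arithmetic or banding code under test. This is deliberate: after a latent
transition the window still sees the old regimen's tail, so the latent step
and the window-derived step legitimately differ during carryover; the
window-wise truth is the correct target for what the pipeline should
recover. Within-step product switches are restricted to realisation pairs
whose union still classifies to the same step, so the zero-noise round trip
is exact: at 500 patients × 5 years (~55,000 prescriptions, ~30,000
post-run-in events) the pipeline recovers 100% of true steps in about 30 s,
and the recovered duration medians preserve the down-greater-than-up dwell
asymmetry.

## Scope and limits

The generator emulates structure, not epidemiology: dwell means, step
occupancies and product mixes are plausible but not calibrated to any
population, and it emits neither the excluded record types (nasal sprays,
deletion notes) nor out-of-period rows — those paths are exercised by
constructed fixtures in the test suite. The catalogue and thresholds are an
editable reconstruction for UK-licensed products; users should substitute
local formularies. Prescription records show what was prescribed, not what
was taken; the derived step is an upper bound on treatment actually
received, and the 25% continuation-capture leniency is part of the method,
not an artefact.
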