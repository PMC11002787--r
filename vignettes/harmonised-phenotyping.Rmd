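---
title: "Harmonised EHR phenotyping across three source dialects: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonised EHR phenotyping across three source dialects: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respcohort)
```

`respcohort` builds asthma, COPD and ILD cohorts with harmonised derived
variables from primary-care records arriving in three structurally
different source dialects, and validates every stage on a synthetic
population with known latent truth. This vignette is the package's account
of the methods: the rules it implements, the conventions it had to fix
where the methodology leaves room, the parameters that matter, and what
the synthetic validation does and does not demonstrate.

## The three dialects

A `dialect_profile()` captures the structural differences the toolkit
harmonises over:

| | CPRD-like | SAIL-like | DataLoch-like |
|---|---|---|---|
| patient identifier | per GP registration | per person | per person |
| birth granularity | year | ISO week | month + year |
| clinical coding | medcode | Read V2 | Read V2 |
| prescriptions | issued, product-coded | issued, Read-coded | dispensed, BNF-coded, from 2009 |
| events outside registration | not used | kept | kept |
| deprivation | IMD 2019 (1 = least deprived) | WIMD 2019 (1 = most deprived) | SIMD 2020v2 (1 = most deprived) |

The per-registration identifier is the single most consequential
difference: a person who moves practice appears under several identifiers
with disjoint registration windows, each assessed independently, and GP
history re-entered at joining makes first-year "incident" codes
unreliable. Both behaviours are reproduced by the synthetic generator and
handled by the cohort builder.

## Diagnosis dates

Every diagnosis code is classified *incident and prevalent* (could mark a
new diagnosis) or *prevalent only* (disease management — annual reviews,
care plans). Two dates are derived per patient:

* **earliest mention** — the minimum event date over both classes;
* **date of incidence** — the minimum date over incident-classified
  events, set to missing when the earliest mention falls within the first
  year of registration.

"First year" needed a boundary convention: it is implemented as the
half-open interval `[followup_start, followup_start + 1 calendar year)`,
calendar addition being the least surprising reading. The masking rule and
the class split are deliberately the whole of the logic; the selection is
verified against an independent brute-force event scan in the test suite.

## Follow-up, death, demographics

Follow-up runs from registration start (minimum start for per-person
dialects) to the earliest of death, last practice collection /
registration end (CPRD-like) or death, maximum registration end and
extraction date (others). Death resolution is dialect-specific: the
mortality register is primary where available, a register record with a
missing death date contributes its registration-of-death date, and deaths
after the register's coverage end fall back to the internal GP date.

Birth imputation is deterministic per granularity: 1st July of the year,
the Monday of the ISO week, the 1st of the month. Week-of-birth input is
interpreted as an ISO-8601 week because the Monday convention is stated
but the week convention is not; the ISO calendar is the only standard that
makes "the Monday of that week" unambiguous. The resulting error against
latent truth is bounded by 366 / 6 / 30 days respectively, which the
acceptance checks verify over 10,000 random birth dates.

Deprivation quintiles are harmonised to the five descriptive labels
*most deprived … least deprived* because the English scheme numbers its
quintiles in the opposite direction to the Welsh and Scottish schemes;
numeric quintiles never appear in outputs. Ethnicity prefers GP codes,
uses hospital codes only when the GP record is silent, and resolves
conflicts per classification scheme by the modal category with a
most-recent-record tie-break (and an alphabetical final tie-break for
determinism). The broad scheme is implemented with six levels — White,
Black, Asian, Mixed, Other, plus Missing — Missing completing the six
where only five labels are commonly listed.

## Clinical measures

Cleaning is range-based and fully logged: every dropped value carries a
rule name retrievable with `measure_drops()`. The plausible ranges stand
in for supplement-level cleaning tables and live in `measure_config()` so
they can be aligned with any published set:

| quantity | default range |
|---|---|
| BMI | 10–80 kg/m² |
| height | 1.0–2.2 m |
| weight | 20–250 kg |
| FEV1 | 0.1–8 L |
| FEV1 % predicted | 10–150 % |

Smoking events are compiled into a longitudinal record with two cleaning
rules: same-day conflicts resolve by the precedence current > ex > never,
and a "never" after any current/ex is re-coded to "ex" — the conservative
"ever-smoker is sticky" choice.

BMI keeps in-range recorded values and, in the CPRD- and SAIL-like
dialects, derives `weight / height²` on days with a usable weight and no
recorded BMI, using the most recent in-range height on or before the day;
the DataLoch-like dialect uses recorded BMI only. Spirometry keeps the
highest same-day FEV1, attaches a same-day GP-entered percent-predicted
value when present and otherwise derives it via the ERS'93 adult
equations (male `4.30·H − 0.029·A − 2.49` L, female `3.95·H − 0.025·A −
2.60` L). The published method names only age and sex as inputs, but the
reference equations require height; height is therefore used, taken as
the nearest prior cleaned height measurement, and the derivation is
skipped (value left missing) when no height exists. The equations are
recommended for ages 18–70 but applied to all patients for simplicity and
comparability. GOLD stages use the conventional 80/50/30 boundaries, each
boundary belonging to the less severe stage, and are attached to all
percent-predicted values regardless of bronchodilation status, since
post-bronchodilation measurements are too rare in routine data to
condition on.

## Medications

Thirteen drug categories are tracked. Combination detection expands
combination products into their components (LABA_ICS → LABA + ICS, …) and
flags a patient-day as triple therapy when LAMA, LABA and ICS are all
present. Detection runs in every dialect — harmless where single
combination codes exist — so flags are comparable across dialects; this
is what makes product-coded and Read-component renders agree exactly.
Single-category counts attribute a combination product to its own
category only; components contribute to combination detection but are not
additionally counted as single-agent use (a documented convention, since
either choice is defensible). The antibiotics category is whatever the
supplied codelist defines — shipped as a respiratory-relevant toy list —
rather than all antimicrobials, and PDE4 inhibitors and antibiotics are
reported for COPD cohorts only.

## The synthetic generator

`generate_population()` draws a latent population with exact dates:
birth (uniform 1925–2009), death (lifespan ≈ N(85, 12) years), sex (1%
recorded unknown), disease status and onset, smoking/BMI/spirometry
trajectories, prescriptions, ethnicity, deprivation and practice moves
(20% movers, moves uniform over adulthood). `render_dialect()` then
coarsens it into one dialect: exact truth, coarse rendering, so
imputation error is quantifiable exactly.

Defaults are chosen once as clinically plausible study conditions:
prevalences 10% / 5% / 1% for asthma / COPD / ILD; asthma onset mostly in
childhood (60% at ages 1–16, the rest at 18–70); COPD onset ≈ N(65, 10)
truncated to 42–90 years and ILD onset ≈ N(72, 8) truncated to 46–95.
The truncation floors sit several years above the 35/40-year cohort age
thresholds, reflecting that a COPD or ILD diagnosis near the age floor is
clinically rare; it also keeps the thresholds decidable under year-level
birth imputation, whose ±6-month error would otherwise make borderline
ages unrecoverable in principle rather than by defect. ILD subtypes are
drawn with IPF most frequent. When an already-diagnosed person joins a
new practice, a prevalent history code is recorded at registration start
— the very recording behaviour that motivates the first-year incidence
masking, and the reason a fragmented CPRD-like registration history still
identifies the person.

Missingness is injected as independent per-record Bernoulli drops with
per-variable rates (default zero), the simplest controllable mechanism;
no quantitative noise model for real coding behaviour is claimed.
Everything the renderer removes by rule — pre-2009 dispensed
prescriptions, combination products without a Read translation — is
tallied under a named rule in `render_log()`.

What passing the synthetic validation shows: the harmonisation rules are
implemented self-consistently, are exactly invertible at zero noise, and
the three dialects' structural differences are fully absorbed by the
pipeline. What it does not show: robustness to real-world coding error,
free-text, duplicate records, miscoded units, or realistic disease
natural history — the generator makes no attempt at those, and the toy
code vocabulary (tens of codes) does not exercise terminology-scale
mapping.

## Numerical and degenerate-input conventions

* Ages are completed years from the *imputed* (dialect-visible) birth
  date — what a real pipeline could observe — except in truth-side
  expectations, which use exact latent dates.
* `latest_in_window()` treats both window bounds as inclusive; a 5-year
  lookback from 2019-12-31 reads 2015-01-01 to 2019-12-31.
* Same-date ties (heights, GP percent-predicted) resolve to the maximum
  value; modal-category ties resolve to the latest record, then
  alphabetically.
* An empty cohort describes as all-zero tables, not an error; an empty
  classified-event set for a patient is a caller error (the patient
  should have been excluded).
* Death before imputed birth is flagged, not silently repaired.

## Problem sizes

The validation suite runs the full pipeline on 10,000 latent persons
across all three dialects and three diseases, the diagnosis-date oracle
on 1,000 randomised patients, the imputation bounds on 10,000 random
birth dates, and combination-therapy equivalence on every latent person
with a triple-therapy prescription; unit tests use populations of 60 to
2,000. These sizes were chosen as the smallest at which every pathway
(movers, fragmentation, decomposition, masking) is exercised many times
over.

## Known limitations

* Regions are pass-through labels; no LSOA/postcode geography.
* CPRD "acceptable patient" and CHI-validity quality flags are modelled
  as booleans on the synthetic records, not recomputed.
* The shipped code vocabulary and ATC↔Read rows are toy fixtures; real
  dictionary releases plug in through the same CSV schemas.
* No FVC/ratio airflow-obstruction confirmation, pack-years, dose or
  adherence modelling, or child growth-reference BMI.
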