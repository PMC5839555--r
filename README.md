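# cannaphen

Computable phenotyping of marijuana use from the free text of
electronic-medical-record (EMR) notes, with the validation machinery to
measure how well it works.

## The problem

Prospective cohorts for studying the cardiovascular effects of marijuana
are hard to assemble: few screening methods find enough exposed older
adults at acceptable cost. Within a large health system, however,
clinicians routinely document substance use in progress notes. When a
clinician writes a specific psychoactive substance into a note, the
mention usually signals current or former use — not its absence. That
premise turns a plain string search into a recruitment screen.

`cannaphen` implements this screen and everything needed to validate it
against interview self-report:

* **Lexicon matching** — whole-word, case-insensitive search for
  `marijuana`, `cannabis` and `mjx` ("`mj`" ships disabled: it collides
  with temporomandibular-joint "TMJ" abbreviations). Matching is
  deliberately *negation-blind*: "denies marijuana use" still counts as
  a mention, and the validation statistics quantify the consequences.
* **Cohort selection** — ICD-9 coronary-artery-disease codes (default
  roots 410–414), an age band (65–67), and ≥1 visit in a calendar
  window.
* **Classification** — a patient is a *preliminary user* iff any
  enabled term is mentioned in any note dated within the 365-day
  lookback ending at the index date; otherwise a *preliminary
  non-user*.
* **Arm sampling** — a seeded draw of n per arm, followed by removal of
  deceased patients and flagging of patients without contact
  information (sample first, exclude after).
* **Validation statistics** — recruitment disposition accounting, the
  arm × self-report concordance table, predictive values
  (PPV = share of the term-positive arm confirmed by interview, against
  past-month, past-year, or lifetime self-report), enrichment
  statements, Fisher-exact / chi-square association tests, and
  baseline-characteristics group summaries.
* **Exposure quantification** — joint-years, where one joint-year is
  one joint per day for 365 days (`joint_years(j, d) = j * d / 365`),
  plus use-pattern gradation summaries.
* **A synthetic EHR generator** — templated clinical notes, a latent
  truth model (lifetime ⊇ past-year ⊇ past-30-day use), a documentation
  model linking true use to in-window mentions, confounder tokens and
  negated mentions, plus interview and exposure simulators. It has a
  probabilistic mode and an exact-count planting mode, so the whole
  pipeline is testable without any protected health data.

## Worked example

The packaged demo study plants the reference accounting exactly — a
210-patient cohort with 62 term-positive patients, a 51 + 51 arm draw
with 3 sampled patients deceased and 2 without contact information, and
interview cells planted per arm — then runs the full pipeline on it:

```r
library(cannaphen)
report <- run_pipeline(demo_config(seed = 1), quiet = TRUE)
report
```

```
== Cohort and preliminary classification ==
Cohort: 210 patients (diagnosis + age band + visit in window).
Lookback: 365 days ending 2015-12-31.
Preliminary users: 62; preliminary non-users: 148.

== Arm sampling ==
Drew 51 per arm (seed 1).
Deceased removed: 3, leaving 99.
Without contact information: 2, leaving 97 contactable (48 users, 49 non-users).

== Recruitment ==
Contacted 97: completed 69, refused by message 1, refused on call 20, unreachable 7.
Recruitment rate: 71%.

== Concordance: text search vs interview ==
                                       Term in notes (n=35)   No term (n=34)
Self-reported use in the past month    15 (42.9%)             3 (8.8%)
Self-reported use in past year         17 (48.6%)             4 (11.8%)
Self-reported non-use (never)          2 (5.7%)               11 (32.4%)
Ever use                               33 (94.3%)             23 (67.6%)

PPV vs past-month use: 42.9%; vs past-year use: 48.6%; vs lifetime use: 94.3%.
Past-month use enrichment: 8.8% -> 42.9% with keywords present.
Ever-use enrichment: 67.6% -> 94.3%.
Ever-use association (Fisher exact, two-sided): OR 7.67, p = 0.005697.
```

Reading the numbers: of the 35 interviewed patients whose notes carried
a term in the past year, 15 (42.9%) reported past-month use — the PPV
against the past-month reference standard. Among interviewed patients
*without* a term, past-month use was 8.8%, so the keyword screen
enriches past-month use roughly five-fold, and lifetime ever-use rises
from 67.6% to 94.3%. The exposure section (simulated interview data)
summarizes mode and frequency gradations and mean joint-years among
current smokers.

Individual pieces are plain functions on tibbles:

```r
lex <- default_lexicon()
note <- tibble::tibble(patient_id = "P1", note_id = "N1",
                       note_date = as.Date("2015-06-01"),
                       text = "Hx of TMJ pain. Denies MARIJUANA use.")
find_mentions(note, lex)
#> # A tibble: 1 x 7
#>   patient_id note_id note_date  term      start   end matched_text
#>   <chr>      <chr>   <date>     <chr>     <int> <int> <chr>
#> 1 P1         N1      2015-06-01 marijuana    23    32 MARIJUANA
```

(`TMJ` does not match; the negated mention does — by design.)

A thin command-line wrapper with subcommands `simulate`, `classify`,
`sample`, `validate`, `exposure` and `run` is installed at
`system.file("cli", "cannaphen", package = "cannaphen")`.

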