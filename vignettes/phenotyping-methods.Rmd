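---
title: "Methods: mention-based phenotyping of marijuana use and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mention-based phenotyping of marijuana use and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cannaphen)
```

## The phenotype and its premise

`cannaphen` classifies patients as likely marijuana users or non-users
from the free text of their clinical notes using nothing but the
presence of lexicon terms. The premise is behavioural, not linguistic:
when a clinician writes a specific psychoactive substance into a
progress note, the mention almost always reflects current or former use
by that patient. The method therefore does **no** negation detection,
no section segmentation, and no statistical NLP — "denies marijuana
use" counts as a mention. This is a deliberate design decision, and the
package's validation layer exists precisely to measure what that
simplification costs (its false-positive contribution) and buys (its
enrichment of true users in the screened-positive arm).

A patient is a *preliminary user* iff at least one enabled term has a
whole-word, case-insensitive match in at least one note dated within
the lookback window; otherwise a *preliminary non-user*. Patients with
no notes classify as non-users: the phenotype measures documented
evidence, and the interview is the arbiter of truth.

## Lexicon and matching rules

The default lexicon enables `marijuana`, `cannabis` and `mjx`; `mj` is
retained but disabled because it collides with temporomandibular-joint
("TMJ") abbreviations. Keeping the discarded term in the config (rather
than deleting it) makes the decision auditable and reversible.

Matching details, all of which needed an explicit convention:

* **Word boundary** = transition between alphanumeric and
  non-alphanumeric characters, with digits counting as word characters.
  So `TMJ` never contains a whole-word `mj`, and `mjx2` does not match
  `mjx`. This is the strictest reasonable boundary rule and was chosen
  to shut off TMJ-style false positives at the matcher level.
* **Case**: matching is case-insensitive by default (clinical notes mix
  `MARIJUANA`, `Cannabis` and lowercase freely); a case-sensitive mode
  exists for audit.
* **Unicode**: text is NFC-normalized before matching.
* **Hyphenation/line-breaks are not bridged**: `mari-\njuana` does not
  match. The reference search workflow is a literal string-search
  facility, and bridging would silently change offsets.
* Mentions are reported with 0-based `[start, end)` character offsets,
  sorted, and non-overlapping.

The matcher is tested against a brute-force scanner that checks every
substring position with explicit boundary tests, on randomized texts
mixing dictionary words, terms, confuser tokens (`TMJ`, `cannabinoid`,
`marijuanas`, `mjx2`) and punctuation.

## Cohort, window, and sampling conventions

* **Cohort filter**: any diagnosis code whose exact value or 3-digit
  root falls in the configured coronary-artery-disease set (default
  410–414 — the conventional ischemic-heart-disease range; no canonical
  list exists, so this is configuration), age 65–67 inclusive at the
  index date, and at least one visit inside the calendar window,
  inclusive on both ends. "At least one visit" is the reading adopted
  for the qualifying-visit requirement. Age is an integer registry
  attribute rather than being derived from a birth date.
* **Lookback window**: "past 12 months" is the 365 calendar days ending
  at and including the index date, i.e. `[index − 364, index]`. The
  boundary tests pin this down: a mention at `index − 364` counts, at
  `index − 365` it does not. The index date is a single study-level
  date (default 2015-12-31), not per-patient.
* **Arm sampling**: `n_per_arm` (default 51) drawn uniformly without
  replacement from each preliminary arm with a seeded RNG (the seed is
  recorded in the result); *then* deceased patients are removed, *then*
  patients without contact information are set aside. The
  sample-first/exclude-after order mirrors how recruitment actually
  proceeds and is what makes the retained-99 / contactable-97 style of
  accounting come out of drawn samples rather than the frame.

## Validation statistics

The concordance table cross-tabulates the two arms against four
*overlapping* self-report categories: past-30-day use, past-year use,
lifetime never-use, and lifetime ever-use. Past-30-day ⊆ past-year ⊆
ever is enforced as a validity invariant, and the never-use row is
defined as the arm total minus ever-use — the rows are not a partition
and deliberately so; only ever/never partition the arm. A predictive
value is `100 × cell / arm_total`; for the term-positive arm this is a
PPV whose reference standard (past-month, past-year or lifetime
self-report) is a parameter, because a keyword screen has no single
natural gold standard. Enrichment returns the negative-arm rate first
so the natural sentence ("rose from x% to y%") reads off directly.

Percentages are rounded **half-up** to one decimal (15/35 = 42.857 →
42.9; `base::round` would bankers-round 42.85 to 42.8), and the
recruitment rate is displayed as an integer percent (69/97 → 71%).
These display rules are part of the contract and are tested.

The headline association test is Fisher's exact test, two-sided
(cells are small); Pearson chi-square with and without Yates continuity
correction are available as alternatives. The implementation delegates
to `stats::fisher.test`/`stats::chisq.test`; the test suite verifies
Fisher p-values against an independent exhaustive hypergeometric
tail-sum enumeration over *all* 2×2 tables with total n ≤ 40. The
validation study's ever-use table `[[33, 2], [23, 11]]` yields
p ≈ 0.0057 under Fisher's exact test, p ≈ 0.0047 under the uncorrected
chi-square and p ≈ 0.0117 with Yates correction — the package reports
the p of whichever test is asked for, privileging the exact one by
default, rather than targeting any externally quoted value.

Baseline-characteristics tables are produced by `group_summary()`:
means for numeric covariates, percentages for binary/categorical ones,
per level of a grouping flag, with no hypothesis tests attached —
small-sample baseline comparisons are descriptive.

## Exposure quantification

One **joint-year** is one joint per day for 365 days (the marijuana
analogue of pack-years), so over a one-year recall window
`joint_years = joints_per_day × days_used / 365` — linear in each
argument, and exactly `j` for a full year at `j` joints/day. Only
smoked use has a joint equivalent; edibles, vaping and topicals carry
no joint-year contribution. Frequency categories are mapped to
representative days/year for simulation and arithmetic (daily = 365,
at least weekly but not daily = 104, 2–3 per month = 30, less often =
12); these constants live in a packaged YAML config, not in code,
because they are modelling choices a study might reasonably revise.

## The synthetic-data generator

The generator emulates the statistical structure the validation design
assumes, with a latent truth model per patient:

* nested use flags: `P(ever) = 0.55`, `P(past-year | ever) = 0.30`,
  `P(past-30d | past-year) = 0.80`. These defaults put past-year use
  near 16% and, through the documentation model, the term-positive
  fraction near 30% of the cohort — the regime the validation study
  operates in for 65–67-year-olds with coronary disease.
* a documentation model: a past-year user's use is documented with an
  in-window mention with probability 0.85; a patient without past-year
  use acquires a mention (e.g. a historical-use note) with probability
  0.10; independently, *any* patient can acquire a negated mention
  ("denies marijuana use") with probability 0.05. Because matching is
  negation-blind, the probability of classifying positive is
  `1 − (1 − p_doc)(1 − p_neg)` for past-year users and
  `1 − (1 − p_term)(1 − p_neg)` otherwise, which makes the
  false-positive contribution rise monotonically with the negated-
  mention rate — an assertable property documenting the method's known
  limitation. `analytic_mention_model()` exposes the implied Bayes-rule
  PPV, and a 20,000-patient simulation must recover it within three
  Monte-Carlo standard errors.
* note content built from templated clinical sentences (a packaged YAML
  file with a `{term}` slot), with confounder tokens (`TMJ`,
  `cannabinoid`, `cannabidiol`) planted at a configurable rate and
  guaranteed never to match; background and out-of-window mention notes
  exercise the window logic.
* registries that pass the cohort filters by construction, plus a
  configurable number of rows that each fail exactly one filter.

Randomness flows from a single master seed through named sub-streams
(registry, truth, notes, interviews, covariates, exposures), so adding
one generator leaves the others' draws untouched and every output is
byte-reproducible from the seed.

**Exact-count mode.** Published validation results are single realized
datasets, not distributions, so the generator also supports planting
counts exactly: cohort size 210 with 62 term-positives, a 51 + 51 draw
in which exactly 2 sampled users and 1 sampled non-user are deceased
and 2 survivors lack contact information (leaving 99 then 97), and
per-arm interview cells (35 completed: 15/17/33 for past-month /
past-year / ever; 34 completed: 3/4/23). The generator replays the
seeded arm draw through the same internal helper `sample_arms()` uses,
so the planted exclusions land on ids the draw will actually select for
*any* seed. The demo configuration (`demo_config()`) is exactly this
study, and the acceptance script re-derives every headline quantity
from it at run time.

**What the simulation does not emulate**: real clinical language
(templates are short single sentences), per-note metadata (authors,
note types, service locations), correlated documentation (e.g. one
clinician repeatedly copying forward a substance-use paragraph),
drift over time, and truthfulness of self-report beyond a single
symmetric misreport rate. Passing tests therefore demonstrate the
*machinery* is correct under the stated statistical assumptions — they
do not certify field performance on real notes, which is exactly why
the interview-validation design exists.

## Numerical and degenerate-input conventions

* Empty note text, patients with zero notes, zero completed interviews
  and empty exposure sets are all defined (empty mention list,
  non-user, all-zero table, explicit undefined-rate errors
  respectively) rather than silent NAs.
* Rates with zero denominators raise a typed `undefined-rate` error.
* Degenerate 2×2 tables (a zero margin) are rejected before testing.
* File interchange is plain text (JSONL for notes, CSV otherwise), each
  file beginning with a `#` provenance comment (package version, seed,
  config hash) that all readers skip; malformed rows are reported with
  their line numbers.

## Problem sizes used in the test suite

Property tests run at sizes chosen to make their statistical assertions
sharp but cheap: 1,000 randomized texts for matcher/oracle equivalence,
exhaustive Fisher verification over all 2×2 tables with n ≤ 40, a
20,000-patient cohort for PPV parameter recovery (3 Monte-Carlo SEs),
150 seed replicates for the interview-completion expectation, and
2,500-patient cohorts at three negated-mention rates for the
false-positive monotonicity check. The end-to-end exact-count study
(210 patients) runs in well under ten seconds.

## Known limitations

* Negation blindness caps the past-month PPV well below 100% by
  construction; the method is a *screen*, not a diagnosis.
* The lexicon is three literal strings; misspellings ("marihuana"),
  slang, and hyphen-broken tokens are missed. Extending the lexicon is
  a config change, but each addition needs a TMJ-style collision check.
* The 12-month window anchors to a single study-level index date; a
  per-patient anchor (e.g. last visit) would change boundary cases.
* ICD-9 only; mapping to ICD-10 cohorts is out of scope.
* Joint-years ignore potency and non-smoked routes entirely.
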