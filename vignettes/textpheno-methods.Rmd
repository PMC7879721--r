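---
title: "Methods: digital phenotyping of therapy message transcripts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: digital phenotyping of therapy message transcripts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Telemental-health platforms accumulate large corpora of timestamped free-text
messages between patients and therapists, alongside brief structured intake
instruments (the 7-item GAD-7 anxiety questionnaire and the 9-item PHQ-9
depression questionnaire, both scored 0–3 per item and totalled by
summation). When a population-level stressor arrives — the motivating case is
the COVID-19 pandemic — two questions follow: did intake symptom severity
shift, and which parts of patients' vocabulary move together with explicit
mentions of the stressor? The second question matters clinically because the
co-moving vocabulary can surface symptoms (insomnia, grief, paranoia,
compulsions, ...) that the structured anxiety/depression instruments never
ask about.

`textpheno` implements this analysis as a five-stage pipeline, plus a
synthetic-corpus generator with planted ground truth so that every stage can
be validated by recovery rather than by eyeballing.

## Pipeline stages

### 1. Seed-keyword screen

Messages are flagged for a small lexicon of literal substrings — by default
`corona`, `virus`, `covid`, `pandemic` — matched case-insensitively as plain
substrings, so that "corona" and "virus" both hit "coronavirus". We chose
substring over word-boundary matching because a boundary-anchored match
cannot produce the small-but-nonzero pre-pandemic incidence that loose
matching of "virus" (antivirus, viral, ...) does; a `word_boundary` flag is
available for stricter semantics. From the flags we derive:

* a **monthly incidence table** (percentage of each month's messages
  containing each pattern, 4 decimal places, half-away-from-zero rounding;
  months without messages are absent rather than zero),
* the **transcript mention rate** (a transcript — all messages of one
  patient — counts as mentioning iff any of its messages is flagged;
  1 decimal place), and
* the **daily mention signal**: per calendar day with at least one message,
  the proportion of that day's messages flagged. Days with no messages are
  *missing*, not zero — imputing zeros would inject artificial variance into
  the trajectory correlations downstream.

### 2. Intake score trends

Totals are the instruments' published sums; incomplete questionnaires are
excluded rather than imputed. The rolling series is a **trailing 14-day
pooled mean** (every intake in `(d − 14, d]` weighted equally). Trailing
rather than centered is a convention of this package — it keeps each day's
value a function of the past only — and pooling stabilises low-volume days.

The pre/post severity shift is estimated as a difference of means between an
explicit baseline window and a comparison window. Because the reference
analysis reports a mean difference with a 95% CI and a p-value without naming
a method, we document our own defaults: a **percentile bootstrap over
patients** (default 10,000 resamples, seeded, independent within each arm)
for the CI, and **Welch's unequal-variance t test** for the p-value. Both
windows are configuration, not hard-coded dates, so "same calendar span of
prior years" baselines are expressed the same way as "the two months before
the changepoint". When both arms are constant the Welch statistic is
undefined; we return the limiting p-value (1 for equal means, 0 otherwise).

### 3. TF-IDF trajectory screen

Each calendar day's messages are pooled into one "text day" document.
Tokenization lowercases, strips punctuation characters from
whitespace-delimited tokens ("COVID-19" → `covid19`), and emits unigrams and
bigrams by default (`n_max = 2`; the field's "words and phrases" usage
implies order > 1 without fixing it). N-grams never cross message
boundaries. Terms seen on fewer than `min_df = 3` distinct days are dropped:
a Pearson correlation over fewer than 3 support points is meaningless.

The TF-IDF variant is raw count × smoothed log idf,

$$w_{d,t} = c_{d,t}\left(1 + \ln\frac{1+N}{1+\mathrm{df}_t}\right),$$

with **no per-day normalization**. The smoothing keeps the idf finite and
positive; skipping row normalization keeps each term's trajectory
proportional to its counts, which is what we want to correlate. (Per-term
idf is a constant multiplier and cannot change a Pearson correlation; it is
retained because the weighted matrix is also an exported artifact.)

Each term's trajectory is correlated with the daily mention signal over
their common days (Pearson r, two-sided p from the exact t transform on
n − 2 degrees of freedom). Zero-variance trajectories are skipped with a
warning. Selection is Benjamini–Hochberg step-up at FDR `q = 0.01` — "false
discovery rate threshold" names a criterion, not a procedure, and BH is the
canonical default — with survivors partitioned by the sign of r.

### 4. Topical categories

Selected terms are assigned to exactly one of eleven topical categories
(confusion/negative emotions, health/medical, work/economic,
technology/internet, cleaning/hygiene, government/leadership,
traveling/shopping, party/celebration, positive emotion/love,
friends/children, optimism) by a transparent cue-word lexicon shipped as
editable JSON. A category's score is the number of its cue stems
prefix-matching any token of the term; the argmax wins, ties break to the
lexicographically first category name, and a zero score everywhere means
unassigned. An embedding-derived categorizer could be swapped in behind the
same single-category contract; the packaged lexicon keeps the stage
deterministic and testable. Breakdown percentages are integer-rounded
(half away from zero) over the full input term set. Note that integer
rounding only guarantees the percentages of an m-category exhaustive
breakdown to sum within ±m/2 of 100; for breakdowns of realistic size they
land within ±1.

### 5. ICD-10 symptom map

Selected terms are compared against a packaged symptom-descriptor lexicon
covering acute stress (F43.0), PTSD (F43.1 — sharing the acute-stress
phenomenology), paranoia (F22), grief (Z63.4), insomnia (G47.00), panic
(F41.0), agoraphobia (F40.00), nonsuicidal self-injury (Z91.5),
obsession-compulsion (F42.9), hypochondriasis (F45.21), anxiety (F41.9),
and a COVID-19-specific bucket. A term supports a code iff any of its
tokens prefix-stem-matches (shared stem ≥ 3 characters, either direction)
any content token of any descriptor phrase; function words are excluded
from content tokens so "the"/"about"/"of" can never carry a match. A term
may support several codes — acute stress and PTSD legitimately share
phrases — and unmatched terms are reported as a list for human clinical
inspection, which is deliberately out of scope for the software.

## The synthetic generator

The generator emulates exactly the statistical structure the analysis
assumes, nothing more:

* **Corpus geometry.** `n_patients = 200` patients (one transcript each)
  observed 2020-01-01 to 2020-06-09 with a changepoint at 2020-03-01 and an
  analysis window of the 101 days from the changepoint on. Message counts
  per patient-day are Poisson(0.5) (a few messages per week, a realistic
  asynchronous-therapy cadence); message lengths are Poisson(20) words,
  minimum 1.
* **Mention process.** Each message is independently in "mention mode" with
  probability 0.001 before the changepoint, ramping linearly to 0.30 over 30
  days and flat thereafter. A mention-mode message carries one uniformly
  chosen seed keyword as a literal token, making the keyword screen's ground
  truth exact. Near-zero pre-changepoint incidence mirrors the verification
  that seed words were essentially absent before the pandemic era.
* **Vocabulary strata.** 20 covid-associated, 20 anti-associated and 160
  neutral filler words, drawn uniformly in ordinary messages. In
  mention-mode messages the covid-associated words are up-weighted
  (`assoc_boost = 8`) and the anti-associated down-weighted
  (`anti_suppress = 0.2`). The boost was calibrated by a power analysis of
  the screen itself: with ~100 messages/day, the weakest planted term's
  expected trajectory correlation must clear the BH threshold, which is
  severe here — with only a few dozen true positives among ~30,000 tested
  terms the effective threshold is near `q·k/m ≈ 10⁻⁵` — so the design
  places the weakest planted term's p-value orders of magnitude below it
  rather than at a knife edge. Anti-associated suppression is bounded (a
  word's frequency cannot fall below zero), so anti terms carry a weaker
  signature and are only occasionally selected; when they are, their
  correlation sign must be negative, which is exactly the sign-fidelity
  property the tests assert.
* **Assessments.** One GAD-7 and one PHQ-9 intake per patient, item
  responses Binomial(3, mean/3) around an item-level mean of 1.2, which hits
  the configured mean exactly and keeps every response in {0..3} by
  construction. Intakes on/after the changepoint use a shifted mean:
  +0.2 per GAD-7 item (a planted total shift of 1.4 points, the order of
  magnitude of the peak-period anxiety shift the method is meant to detect)
  and 0 for PHQ-9 (the planted null). In `simulate_cohort()` intakes are
  dated at each patient's first message; standalone
  `simulate_assessments()` draws intake dates uniformly, because it must be
  reproducible without the corpus while the corpus and assessment RNG
  substreams stay independent (so enlarging the corpus never perturbs the
  assessment draws).

What the generator does **not** emulate: real language (bag-of-words only —
the analysis consumes counts), therapist-side messages, assessment dropout,
seasonal or weekly rhythms, and any dependence between a patient's text and
their scores. Passing recovery tests therefore demonstrate that the
*statistical machinery* is correct under the assumed structure, not that the
pipeline's conclusions transfer to any particular real corpus.

## Numerical and degenerate-input conventions

* All printed percentages round half away from zero (base R rounds half to
  even): 4 decimals for monthly incidence cells, 1 for headline rates,
  integers for category breakdowns.
* Correlations are computed column-centered in double precision and clamped
  to [−1, 1]; |r| = 1 maps to p = 0.
* Empty cohorts, empty corpora and months without messages are empty
  results, not errors; an all-unflagged corpus gives an all-zero incidence
  table; fewer than 3 paired days, windows with fewer than 2 intakes, and
  overlapping shift windows are errors.
* Determinism: every stochastic component draws from a named substream of
  one master seed, so identical configuration reproduces byte-identical
  corpora, assessments and reports.

## Validation problem sizes

The shipped test suite validates BH selection against an exhaustive step-up
oracle (1,000 random p-vectors of length ≤ 12), Pearson inference against
the direct formula (1,000 random trajectories, 10⁻¹² tolerance), the
keyword screen against a character-scan recount on random corpora of ≤ 100
messages, planted-vocabulary recovery on the default conditions over seeds
1–20 (sensitivity ≥ 0.9 for covid-associated terms, ≤ 5% neutral selection,
full sign fidelity for selected anti-associated terms), and shift recovery
over 100 replicates with 2,000 intakes per arm (CI coverage of the planted
1.4-point shift ≥ 90%, and p > 0.05 in ≥ 90% of planted-null PHQ-9
replicates). These sizes were chosen as the smallest at which the binomial
noise of the recovery rates is well inside the asserted margins.

## Known limitations

* Substring seed matching over-counts morphological neighbours ("antivirus")
  by design; use `word_boundary = TRUE` for stricter screens.
* Global pooling of all patients into one text day (the package's reading of
  the ambiguous "text day" unit) means prolific patients dominate a day's
  vector; per-patient day documents would be a different, unimplemented
  convention.
* The category and symptom lexicons are compact, editable stand-ins built
  for transparency; they make no claim to the coverage of an
  embedding-derived categorizer or of the full ICD-10 text.
* The shift estimator is a two-window mean comparison; it does not model
  within-patient longitudinal structure, seasonality, or case-mix change
  between windows.
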