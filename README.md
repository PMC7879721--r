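# textpheno

Digital phenotyping of therapy message transcripts.

Telemental-health platforms hold two complementary data streams: free-text
messages between patients and therapists, and brief structured intake
instruments (GAD-7 for anxiety, PHQ-9 for depression). When a
population-level stressor such as a pandemic arrives, `textpheno` answers
two questions from those streams:

1. **Did intake symptom severity shift?** Totals are the instruments'
   published sums; the shift between a baseline and a comparison window is
   estimated as a difference of means,
   `Δ = x̄_comparison − x̄_baseline`, with a percentile bootstrap 95% CI over
   patients and a Welch two-sample p-value, plus trailing 14-day rolling
   intake averages for visual trend inspection.
2. **Which vocabulary moves with explicit mentions of the stressor?**
   Messages are screened for seed keywords (`corona`, `virus`, `covid`,
   `pandemic` by default, case-insensitive substrings). Each calendar day's
   messages are pooled into a "text day", counted as unigrams and bigrams,
   and weighted by a smoothed TF-IDF,
   `w(d,t) = count(d,t) · (1 + ln((1+N)/(1+df(t))))`. Every term's daily
   trajectory is Pearson-correlated with the daily proportion of
   mention-flagged messages, and terms are selected by Benjamini–Hochberg
   step-up at FDR q = 0.01, split into positively and negatively correlated
   sets. Selected terms are then assigned to topical categories by an
   editable cue-word lexicon and mapped onto ICD-10 symptom descriptors
   (insomnia G47.00, acute stress F43.0, PTSD F43.1, panic F41.0, grief
   Z63.4, paranoia F22, and so on).

A synthetic-corpus generator with planted ground truth (three vocabulary
strata, a mention-probability ramp at a changepoint, a planted GAD-7 shift
and a PHQ-9 null) makes every stage testable by recovery. See the methods
vignette (`vignettes/textpheno-methods.Rmd`) for the model, parameter
defaults and design decisions.

## Worked example

```r
library(textpheno)

cfg <- generator_config(seed = 42)          # 200 patients, Jan 1 - Jun 9 2020,
                                            # changepoint Mar 1
report <- run_pipeline(pipeline_config(simulate = cfg, n_boot = 2000,
                                       seed = 42))
print(report)
#> == textpheno pipeline report ==
#> transcripts mentioning a seed keyword: 100.0% (200/200)
#> GAD7 shift: 1.95 (95% CI 1.25 to 2.59), P = <0.001
#> PHQ9 shift: 0.03 (95% CI -0.77 to 0.82), P = 0.935
#> term screen: 32072 tested, 24 positive, 6 negative at q = 0.01
#> recovery: covid-term sensitivity 1.000, neutral selected 0.0000, anti in negative NA
#> seed 42, config 0c992a0f
```

Reading the report: every simulated transcript mentions a seed keyword at
least once over the three post-changepoint months; the GAD-7 intake mean
rises by 1.95 points (the generator planted a 1.4-point shift, well inside
the bootstrap CI at this cohort size) while the planted-null PHQ-9 stays
flat; and of ~32,000 tested terms the screen selects 24 positive ones — all
20 planted covid-associated words plus the four seed keywords themselves —
with no neutral word selected. The monthly incidence table shows the
near-zero pre-changepoint seed-word rates:

```r
head(report$monthly_incidence, 3)
#>   year month n_messages corona  virus  covid pandemic
#> 1 2020     1       3009 0.0000 0.0000 0.0000   0.0000
#> 2 2020     2       2872 0.0348 0.0348 0.0348   0.0348
#> 3 2020     3       3109 4.0206 3.1200 3.8919   3.8276
```

The lexicon stages operate on any term set, e.g. real vocabulary:

```r
terms <- c("quarantine cleaning", "lost my job", "zoom fatigue", "cant sleep",
           "nightmares", "panic attacks", "birthday party", "hopeful")
category_percentages(assign_categories(terms))
#>              category n percentage
#> 1    cleaning_hygiene 1         13
#> 2            optimism 1         13
#> 3   party_celebration 1         13
#> 4 technology_internet 1         13
#> 5       work_economic 1         13
#> 6          unassigned 3         38
match_symptoms(terms)
#> ICD-10 symptom matches over 8 terms (5 unmatched)
#>   G47.00   Insomnia                         1 term(s)
#>   F43.0    Acute stress                     1 term(s)
#>   F43.1    Posttraumatic stress disorder    1 term(s)
#>   F41.0    Panic                            1 term(s)
#>   F40.00   Agoraphobia                      1 term(s)
```

A thin command-line wrapper over the same functions ships at
`inst/cli/textpheno.R` (subcommands `run`, `simulate`, `screen`, `trends`,
`screen-terms`, `categorize`, `icd10`).

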