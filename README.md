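# screenome

Daily suicide-risk profiling from passively captured smartphone screen text
("screenomes") and ecological momentary assessment (EMA) self-reports.

## The problem

Intensive time-sampling studies of suicide risk pair two streams. EMA
surveys (6 signal-contingent prompts/day within 2-hour windows of a 12-hour
block, 30-minute validity) measure momentary ideation, planning, desire and
risk factors directly — but compliance collapses exactly when risk peaks.
Screen capture (one screenshot every 5 seconds while the phone is in use,
with text extracted by OCR) is burden-free and keeps flowing through a
crisis, but arrives as a raw stream of tens of thousands of screens that
must be reduced to interpretable per-day series. `screenome` is the
reduction pipeline and the join:

- **Text**: OCR-confidence filtering (< 0.70 removed), normalization
  (case reduction, punctuation/digit removal, lemmatization), removal of
  screens that render the survey itself, day-level random sampling.
- **Dictionary scoring**: greedy longest-first, non-overlapping phrase
  matching against normalized lexicons; daily counts and day-over-total
  ratio scores `r_d = c_d / Σ_d c_d`; hourly within-day counts; top-k
  endorsed words; app-category tagging (SMS / Meta keywords); daily sums of
  externally predicted social-content probabilities.
- **EMA metrics**: compliance (overall %, response-day %, mean prompts per
  response day), summed composites (ideation 4–20, planning 3–15, desire
  2–10), binary risk-factor day series, and person-specific "high" flags at
  the interpolated 90th percentile (`value ≥ Q̂₀.₉`, quantile type 7).
- **Usage metrics**: daily capture counts, day×hour matrices with the
  720-captures/hour capacity, use fractions (`count·5/3600`; 360 captures =
  50% of an hour), intensive-use cells (> 0.5), collection hours.
- **Profiles**: person-day tables aligned so relative day 0 is the first
  hospitalization day, with tricube local-linear (loess) trend curves.
- **Synthetic data**: a seeded generator producing complete study bundles
  (usage sessions, screen text with lexical injections, prompts/responses
  with a compliance ramp declining into the crisis, timelines) with ground
  truth returned for recovery tests — real data of this kind are protected
  and cannot ship.

## A worked example

```r
library(screenome)

cfg <- synth_config(usage = list(sessions_per_day = 4, session_mean_min = 10))
res <- profile_pipeline(cfg, seed = 7)

res$compliance[, c("prompts_completed", "overall_pct", "response_day_pct")]
#>   prompts_completed overall_pct response_day_pct
#> 1                98        58.3             60.5

res$profile[26:30, c("study_day", "relative_day", "n_screens", "pain_count",
                     "pain_ratio", "prompts_completed", "pain")]
#>   study_day relative_day n_screens pain_count pain_ratio prompts_completed pain
#> 1        26           -3       711         31 0.02553542                 0   NA
#> 2        27           -2       280         21 0.01729819                 2   91
#> 3        28           -1      1308        300 0.24711697                 2   57
#> 4        29            0      1379         60 0.04942339                NA   NA
#> 5        30            1       362         18 0.01482702                NA   NA

top_k_words(res$screens, cfg$text$lexicons$risk, k = 5)
#>   phrase count
#> 1   numb   264
#> 2 guilty   256
#> 3  alone   250
#> 4   trap   244
#> 5    cry   241
```

Reading the profile: the crisis is on study day 29 (`relative_day` 0). The
pain-lexicon ratio spikes on crisis-eve (day 28: 0.247, a five-fold
injection over baseline — the configured ground truth), phone use rises
into the crisis (`n_screens`), while the EMA stream thins out and then
stops (`prompts_completed` 0–2, then no prompts after day 28): the passive
stream keeps reporting exactly where the active one goes quiet. Top words
are reported in normalized (lemmatized) form, e.g. `trap`, `cry`.

## Scope

Dictionary word lists ship as small fixtures (the crisis lexicon is a
clearly marked synthetic stand-in for a non-redistributable published
dictionary). OCR itself, screenshot capture/encryption infrastructure,
image-classifier training, and statistical modeling of the resulting
profiles are out of scope; the package produces the descriptive series and
tables such analyses start from. It is a research tool, not a clinical
instrument.
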