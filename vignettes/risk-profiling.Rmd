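---
title: "Building daily risk profiles from screen text and momentary self-reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building daily risk profiles from screen text and momentary self-reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenome)
```

## The measurement problem

Intensive time-sampling studies of suicide risk combine two data streams
with very different properties. *Active* assessment (ecological momentary
assessment, EMA) asks a participant to answer short surveys several times a
day; it has high face validity but breaks down exactly when it matters most,
because compliance drops during crises. *Passive* assessment captures the
smartphone screen every 5 seconds while the phone is in use and extracts the
rendered text by OCR; it requires nothing of the participant, but the raw
stream (tens of thousands of screenshots per person-week) must be reduced to
interpretable daily series before it says anything about risk.

`screenome` implements that reduction and the joint person-day profile:

1. **Text pipeline** — OCR-confidence filtering, normalization
   (case reduction, punctuation/digit removal, lemmatization), removal of
   screens that render the survey itself, and day-level random sampling for
   qualitative audits.
2. **Lexicon scoring** — dictionary counts of normalized phrases per day and
   per hour, ratio scores, top-endorsed words, app-category tagging, and
   aggregation of externally predicted social-content probabilities.
3. **EMA metrics** — compliance, summed suicide composites (ideation,
   planning, desire), risk-factor series, and person-specific 90th-percentile
   flags.
4. **Usage metrics** — phone-use quantification from capture timestamps
   alone: daily counts, day-by-hour matrices, use fractions, intensive-use
   flags.
5. **Profile assembly** — hospitalization-aligned person-day tables with
   loess trend curves.
6. **Synthetic data** — a generator producing complete, internally
   consistent study datasets with known ground truth, because the real
   participant data such studies collect are protected and cannot ship with
   an analysis package.

## Conventions and key parameters

**Capture cadence.** One screenshot per 5-second slot while the phone is in
use. One hour therefore holds at most 720 captures; 360 captures correspond
to 50% of an hour, and `collection_hours(n)` is `n * 5 / 3600`. Duplicate
captures within one slot are collapsed with a warning.

**Local time.** Every event carries one fixed UTC offset per person, and all
day/hour binning happens in the participant's local wall clock. A fixed
offset (rather than a named timezone) makes day boundaries unambiguous and
avoids daylight-saving discontinuities inside a study window; if a study
spans a clock change, the offset of the majority period should be chosen.
Days start at local midnight.

**OCR confidence.** Blocks extracted with confidence below 0.70 are removed
(`filter_confidence()`, strictly "less than": a block at exactly 0.70 is
kept). The OCR engine itself is a pluggable boundary — the pipeline consumes
`(text, confidence)` pairs from any source, including the generator.

**Normalization.** Tokens are produced by splitting on any non-alphabetic
character after lowercasing, then lemmatized. The default lemmatizer is the
package's own compact rule-based suffix stripper (irregular-form table,
plural/-ed/-ing rules with doubled-consonant undoing and final-e
restoration). Its job is internal consistency, not linguistic perfection:
dictionary matching only requires that screen text and lexicons pass through
*the same* normalizer, which is why lexicons are stored pre-normalized.
Stop-words are not removed — "like" is an app-identification keyword.

**Phrase matching.** `match_phrases()` scans left to right and counts
non-overlapping occurrences, preferring the longest entry at each position
(alphabetical among equal lengths). This prevents double-counting a phrase
and its sub-phrase ("end it all" vs "end") at one position while still
letting both match elsewhere. A phrase listed in several lexicons counts in
each independently.

**Ratio scores.** Daily dictionary scores are displayed as each day's count
divided by the total over the whole observation window, so a series sums to
exactly 1 (or is identically 0). The denominator is the full window, not the
days with nonzero counts.

**EMA design.** 6 prompts/day for 28 days, each delivered uniformly at
random within its 2-hour window of a 12-hour participant block (default
start 09:00), valid for 30 minutes with a 15-minute reminder. A response
after expiry is invalid — compliance is defined over completed-within-window
prompts, so `read_ema()` rejects late responses rather than silently
counting them. A "response day" is a study day with at least one completed
prompt. Reported percentages are rounded half-away-from-zero to one decimal;
raw values are kept alongside.

**Composites.** Likert items are coded 1–5 (the anchors are study-specific;
only the 5-point structure matters here), so the summed composites range
4–20 (ideation, 4 items), 3–15 (planning, 3 items) and 2–10 (desire,
2 items). Missingness is listwise per composite: any missing constituent
makes that composite missing for that response.

**High flags.** "High" is person-specific: at or above the 90th percentile
of the person's own nonmissing values, with the percentile computed by
linear interpolation between order statistics (`stats::quantile()` type 7).
On the series 1..10 the threshold is 9.1 and only the 10 is flagged; on a
constant series every value equals the threshold and all are flagged.

**Loess.** Trend curves use locally weighted degree-1 regression with
tricube weights over the `ceiling(span * n)` nearest neighbours
(span 0.75 by default, configurable; no robustness iterations). The
implementation is self-contained so the neighbourhood rule is fully
specified: constants and straight lines are reproduced exactly, the fit
commutes with affine transforms of the response, and each fitted value
equals an explicit tricube-weighted normal-equations solve at that point.
Smoothing parameters are reported as package defaults in output metadata,
not as estimates of any published figure's settings.

**Alignment.** Comparative displays re-index study days so that relative
day 0 is the *first* day of hospitalization; `align_to_event()` keeps
`study_day` so the mapping is invertible. Profiles zero-fill count-derived
columns (absence of collection is an observed zero) but preserve EMA
missingness (a skipped prompt is information — compliance gaps are
themselves a finding).

## What the generator emulates

`synth_config()` fixes the simulated study conditions:

* **Design**: 35 days of capture, 28 EMA days, crisis on day 29 with a
  4-day hospitalization (the person-A-like default), one fixed UTC offset.
* **Usage**: sessions arrive as a Poisson count per day (default 12,
  mean length 30 min — nominally 6 h/day, realized ≈5 h/day of collection
  after overlapping sessions collapse onto the slot grid), with start hours
  drawn from an intensity profile that increases across the day; screens are
  emitted every 5 s within a session, and overlapping sessions collapse onto
  the slot grid so the 720/hour capacity holds by construction. Phone use
  rises on crisis-eve (multiplier 1.5).
* **Text**: background tokens come from a rank-weighted pseudo-word
  vocabulary (disjoint from every lexicon, also after lemmatization);
  each lexicon phrase is injected as a contiguous token run at
  `base_rate` (0.05/screen) times a per-day multiplier, 5 on crisis-eve —
  the "spike in pain the day before hospitalization" pattern. A configurable
  share of OCR blocks (10%) draws confidence below 0.70. Survey screens
  rendering item wordings are inserted at prompt times so the EMA-screen
  removal step has real work to do.
* **Compliance**: each prompt is answered with a day-specific probability
  following a logistic ramp from 0.6 (a typical clinical-population rate)
  down to a floor of 0.1 reached three days before the crisis. The decline
  is the documented phenomenon; the logistic form is the package's choice —
  any monotone decline would be legal.
* **Items**: a latent severity trajectory rises piecewise-linearly over the
  week before the crisis; ordinal items discretize latent draws through
  fixed cut-points, binary items are Bernoulli, sleep items are asked at the
  morning prompt only, and pain is reported once daily as a rounded normal
  draw (mean 74.4, SD 16.2 by default) clamped to 0–100. Clamping, rather
  than truncation, keeps the realized mean within ~0.4 of the target.

What the generator does **not** emulate: real session-length and
tokens-per-screen distributions (unpublished; the defaults are fixtures),
OCR error structure beyond the confidence mixture, app-level UI layouts,
actual language use, and between-person heterogeneity. Passing tests on
synthetic data therefore demonstrate that the pipeline recovers signals *of
the assumed form* — injection spikes, compliance ramps, usage gradients —
not that those forms describe any real participant.

## Numerical choices and degenerate inputs

* Ratio conservation is exact to 1e-12; an all-zero series maps to all-zero
  ratios rather than NaN.
* `63/(23*6)` is 45.652...; the package reports 45.7 (half-away-from-zero),
  and analyses comparing against a truncated 45.6 should allow 0.1.
* `high_flags()` requires at least 2 nonmissing values; `loess_trend()` at
  least 4, and falls back to a weighted mean where the local design is
  singular (e.g. all in-window x equal).
* Empty inputs flow through: an empty JSON-lines file yields a zero-row
  stream, a prompts-only EMA read yields an empty response table, a
  screen losing all blocks to the confidence filter stays in the stream as
  an empty capture (it still represents 5 s of phone use).
* Mean daily collection hours are *not* compared against published
  per-person values: the published means cannot be reconciled with any
  recoverable denominator (days-with-collection vs full span), so the
  package exposes the slot arithmetic and leaves the denominator to the
  analyst.

## Problem sizes in the test suite

Stochastic suites run at reduced problem sizes chosen once: signal-recovery
uses 8 sessions/day of mean 2 minutes (about 190 screens/day, ~2,300
background tokens/day — comfortably above the 200/day floor at which the
5-fold injection is identifiable), 100 seeds for spike recovery, 200 seeds
for compliance decline, and a 2-session configuration for the byte-identity
pipeline run. Rates, multipliers, thresholds and compliance parameters are
never scaled — only session counts, which set the problem size.

## A worked example

```{r example, eval = FALSE}
cfg <- synth_config(usage = list(sessions_per_day = 4, session_mean_min = 10))
res <- profile_pipeline(cfg, seed = 7)

res$compliance[, c("overall_pct", "response_day_pct", "mean_per_response_day")]
res$profile[26:30, c("study_day", "relative_day", "n_screens",
                     "pain_count", "pain_ratio", "prompts_completed")]

# top endorsed risk words and the within-day spike on crisis-eve
scr <- res$screens
top_k_words(scr, cfg$text$lexicons$risk, k = 5)

# phone-use structure
p <- res$person
m <- hour_matrix(p$events, p$timeline)
mean_hourly_fraction(m)
intensive_hours(m)
```

## Limitations

The shipped lexicons are fixtures: the crisis dictionary in particular is a
synthetic stand-in for an externally developed 227-phrase list that cannot
be redistributed, and dictionary-based scoring inherits all the usual
caveats (the single keyword "text" over-matches app tagging by design, and
no dictionary validated on chat text is automatically valid on screen text).
The package deliberately stops at descriptive profiles — no statistical
modeling or inference on the series is provided, and nothing here is a
clinical decision tool.
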