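---
title: "Scoring methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pwat)
```

This vignette documents the scoring model implemented by `pwat`, the
choices made where the instrument's published description leaves the
design open, and what the synthetic validation does — and does not — show
about behaviour on real facility data.

## The instrument and its answer scales

The instrument is a registry of 133 weighted welfare descriptors for
research macaque facilities, organised into six categories — physical,
behavioural, environmental, training, procedural, and culture of care —
and around thirty subcategories, split across three assessment forms:
per-room observation forms (animal outcome measures), one site-level form
(records and input measures), and culture-of-care personnel interviews.
Every descriptor carries a welfare weight from 1 (low welfare impact) to 5
(high impact).

Two answer scales exist. Graded descriptors are scored from the observed
prevalence of the item or activity: below 25% scores 0 ("rarely
present"), 25–75% scores 1 ("moderately present"), above 75% scores 2
("obviously present"). `proportion_to_score()` implements exactly this
banding; since the printed ranges make the middle band closed, 0.25 and
0.75 both map to 1, and only strictly larger values map upward. Yes/no
descriptors score 2 or 0. A non-applicable (NA) answer is reserved for
items that are physically impossible to assess (e.g. parental behaviour at
a non-breeding facility) and removes the descriptor from scoring entirely.

Three descriptor roles exist:

* **standard** descriptors form both the earned points and the
  possible-points denominator (`weight × 2` per answered descriptor);
* **bonus** descriptors (outdoor access, remote monitoring, a dedicated
  training programme, telemetry) add `value × weight` to the numerator
  only. This is the only reading under which a facility can exceed 100% —
  which the instrument's design explicitly allows — and it implies an NA
  or unanswered bonus simply contributes nothing;
* the single **penalty** descriptor subtracts one point per singly housed
  animal in a room, capped at 20 points. The per-animal rate is not fixed
  by the published description, only the cap; the default of 1 point per
  animal is the simplest monotone rule consistent with a meaningful
  20-point cap, and both rate and cap are configurable in the instrument
  file's `penalty_config`.

The shipped canonical definition is a *synthetic transcription*: the
structure (133 descriptors, category/subcategory tree, form split, weight
range, bonus and penalty semantics, subcategory maxima equal to the sum of
`weight × 2` over standard descriptors) follows the published design, but
the per-item wording is authored for this package because the original
descriptor table is not redistributable. One compositional choice
deserves note: each category was given several yes/no room-level
descriptors alongside its graded ones. Under the prevalence bands, any
latent quality between 0.25 and 0.75 maps to a graded answer of 1, so
graded items cannot distinguish facilities within that range; yes/no
items, whose expected score varies continuously with quality, carry the
discrimination there. Mixed nominal/graded scales per category are also
what the published instrument describes.

## Scoring, NA handling, and degenerate scopes

For any scope (subcategory, category, total), `score_scope()` computes

* `earned` — `Σ value × weight` over answered standard descriptors,
* `possible` — `Σ 2 × weight` over the same descriptors,
* `bonus` — `Σ value × weight` over answered bonus descriptors,
* `percentage` — `100 × (earned + bonus − penalty) / possible`.

NA removal from both numerator and denominator makes scoring equivalent
to deleting the descriptor from the instrument (a tested invariant). A
scope whose standard descriptors are all excluded has `possible = 0` and
reports an `NA` percentage — undefined, never a division error — and
undefined scopes propagate as `NA` through benchmarks and cross-site
means rather than being silently imputed.

Unanswered descriptors on a submitted form are treated as NA with a
warning, **not** as 0. A zero means "assessed and absent", which is a
substantive welfare finding; silently defaulting missing data to it would
bias scores downward and make a skipped page indistinguishable from a bad
one.

Percentages are computed in full precision and rounded to one decimal
only at the reporting layer.

## Aggregation across rooms, forms, and periods

Room forms and interviews are aggregated at the **descriptor level**: the
effective answer is the mean of non-NA unit answers (three rooms
answering 2, 2, 1 yield 5/3). Aggregating at the descriptor level rather
than averaging per-room percentages keeps descriptor-level gap reporting
exact and makes NA handling well defined; when no answer is NA the two
orders agree anyway (a tested linearity invariant), and duplicating every
room form leaves the assessment unchanged (replication invariance).

The penalty cap applies *within a room*: per-room reductions are capped
at 20 and then averaged across rooms. The alternative (capping the
averaged raw counts) would let one severely affected room dominate; the
within-room reading follows the cap's description and is the default.
The penalty attaches to the facility total only — it is described as a
reduction of the *final* score — with a configuration switch
(`penalty_config$apply_to`) to also apply it to a category.

Categories may mix forms (e.g. physical has room and site descriptors);
points are pooled across the category's descriptors after unit
aggregation, giving one denominator per category.

Annual benchmarking (`benchmark_year()`) averages each percentage and
relative score element-wise across the periods a facility completed; a
single assessment passes through unchanged. Averaging operates on
percentages rather than raw points so that periods with different NA
patterns (different denominators) average sensibly. The facility's
overall score is reported both as the pooled-points percentage
(`overall_percentage`) and through the six relative category scores
(whose sum, `relative_total`, reaches 600 for a maximal facility before
bonus); the published description does not say which single number is
"the" site score, so both are carried side by side.

## Sampling plans

Facilities assess approximately 10% of occupied primate rooms, with a
minimum of three and maximum of ten: `plan_room_sample()` rounds half-up
("approximately 10%") and clamps. Interview counts are only described as
3–6 "depending on number of personnel"; the implemented tier rule,
`ceiling(n / 10)` clamped to `[3, 6]`, is a stand-in chosen to be simple,
monotone, and to reach both endpoints (30 or fewer personnel → 3;
51 or more → 6), with the tier width configurable. Facilities smaller
than the minima assess what they have, with a warning.

## The synthetic campaign generator

`simulate_campaign()` emulates a multi-site, multi-period campaign with
known ground truth. Each facility profile fixes a latent quality
θ ∈ [0, 1] per category, facility size (which drives the sampling plans),
an NA rate applied to NA-eligible descriptors, a single-housing rate, a
uniform observer noise half-width σ, and a probability of skipping a
period. Graded answers are generated as
`proportion_to_score(clip(θ + ε))` with ε ~ U[−σ, σ] — deliberately
routed through the same banding code real assessments use — and yes/no
answers are 2 with probability `clip(θ + ε)`. Penalty counts are binomial
over a configurable animals-per-room constant (default 8, a typical
macaque room census in the absence of a stated one). Generation is fully
deterministic given the seed.

Default profile parameters (σ = 0.05, NA rate 0.05, single-housing rate
0.1) represent a competent assessor with occasional genuinely
non-assessable items and a facility with modest single housing; they are
the regime the validation study uses, not tuning knobs.

Note one consequence of the generative rules: at σ = 0 the graded answers
become an exact deterministic function of θ, but yes/no answers remain
Bernoulli draws, so even noise-free campaigns retain sampling variability
in proportion to the number of rooms and interviews assessed.

The recovery study (`recovery_study()`) is the package's end-to-end
validation: ten facilities with quality evenly spaced 0.3–0.9, σ = 0.05,
two periods, three seeds; the Spearman rank correlation between true
θ and benchmarked category percentage, per category across facilities,
averaged over seeds, is required to reach at least 0.9. At these
conditions the engine recovers the ranking at ≈ 0.95–1.0 per category.

What passing this does **not** show: real assessors are not unbiased
noise around a scalar facility quality — inter-rater differences are
systematic (the published campaign itself saw sites over-score by
misusing NA), descriptors within a facility are correlated in ways a
single θ per category cannot express, and real prevalences are not
uniform. The simulator validates the arithmetic, aggregation, and
pipeline plumbing, not the instrument's construct validity, which only
field use can address.

## Numerical and interface choices

* Band boundaries: closed middle band `[0.25, 0.75] → 1`, from the
  printed ranges; values outside `[0, 1]` are domain errors, not clamped.
* Rounding: half-up for the room-sampling rule (base R's `round()` is
  half-even); report tables at one decimal.
* Gap threshold: descriptors "scoring below 2" — i.e. anything short of
  the maximum — default the gap list; configurable. Gaps order by
  ascending `value × weight` so the heaviest-impact shortfalls lead; ties
  in `suggest_focus()` break toward the subcategory with more possible
  points (the larger programme component).
* Facility anonymisation: cross-site reports label facilities A, B, C, …
  in input order, with `anonymise = FALSE` to disable.
* Reports are pure functions of their inputs (no timestamps), so
  identical inputs give byte-identical documents.

## Problem sizes used in the test suite

The property suites run 1,000 random mini-instruments (≤ 12 descriptors)
against an independent brute-force oracle, plus 100-case suites for the
NA-removal and monotonicity invariants; the recovery study runs 10
facilities × 2 periods × 3 seeds on the full 133-descriptor instrument
(≈ 20,000 simulated answers per seed). These sizes make the whole suite
run in a few minutes on one CPU while keeping the statistical checks
well-powered.

## Known limitations

* The canonical descriptor wording is synthetic; analyses that depend on
  the exact published item text (e.g. translating reports) need the
  original table substituted via `load_instrument()`.
* The interview-count tier rule is a documented stand-in.
* Period labels are free strings; the benchmark groups by leading
  four-digit year and does not parse quarter semantics beyond ordering.
* No statistical testing of site differences is provided, matching the
  instrument's descriptive use.
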