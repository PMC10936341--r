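# pwat

Scoring and benchmarking engine for a weighted welfare-assessment
instrument used with research macaques.

Facilities housing research primates need a quantitative, repeatable way to
assess their behavioural management programmes: not daily husbandry checks,
but a periodic audit that mixes input-based measures (what resources the
animals are given) with outcome-based measures (what the animals — and the
people caring for them — actually show). `pwat` implements such an
instrument end to end: 133 weighted welfare descriptors in six categories
(physical, behavioural, environmental, training, procedural, culture of
care), split across three forms (per-room observation forms, one site-level
records form, and culture-of-care personnel interviews), with the full
scoring arithmetic, room/interview aggregation, annual benchmarking,
audit sampling rules, gap reporting, and a synthetic campaign simulator for
validating the pipeline against known ground truth.

It is intended for animal-welfare scientists and behavioural management
teams who want to run, adapt, or stress-test a descriptor-based welfare
audit across multiple facilities.

## The scoring model

Each descriptor *d* carries a welfare weight *w\_d* ∈ {1,…,5} and receives
an answer *v\_d* ∈ {0, 1, 2, NA}. Graded descriptors are answered from
observed prevalence via fixed bands — rarely present (< 25%) → 0,
moderately present (25–75%) → 1, obviously present (> 75%) → 2 — and
yes/no descriptors score 2/0. For any scope *S* (a subcategory, a
category, or the whole instrument):

```
earned(S)   = Σ_{d ∈ S, standard, v_d ≠ NA} v_d · w_d
possible(S) = Σ_{d ∈ S, standard, v_d ≠ NA} 2 · w_d
bonus(S)    = Σ_{d ∈ S, bonus,    v_d ≠ NA} v_d · w_d
score(S)    = 100 · (earned + bonus − penalty) / possible
```

Non-applicable answers drop out of both numerator and denominator. Bonus
descriptors (e.g. outdoor access) add points without enlarging the
denominator, so scores above 100% are possible. A single penalty
descriptor subtracts one point per singly housed animal in a room, capped
at 20 points per room; across rooms the per-room capped reductions are
averaged, and the result is subtracted from the facility total. Multiple
room forms and interviews are aggregated descriptor-wise (mean of non-NA
answers), annual benchmarks average a facility's assessments (a single
assessment passes through), and the six category percentages double as
"relative scores" summing to at most 600 (before bonus) for cross-site
bar charts.

The shipped instrument definition
(`inst/extdata/pwat_instrument_synthetic.json`) is a synthetic
transcription: it reproduces the published design — 133 descriptors, six
categories, three forms, weights 1–5, bonus/penalty semantics,
self-consistent subcategory maxima — with descriptor wording authored for
this package.

## Worked example

```r
library(pwat)
library(dplyr)

instr <- canonical_instrument()

# simulate a two-facility campaign with known latent quality
profiles <- bind_rows(
  facility_profile("siteA", theta = 0.85, n_rooms = 120, n_personnel = 70),
  facility_profile("siteB", theta = 0.55, n_rooms = 45,  n_personnel = 30))
forms <- simulate_campaign(profiles, instr, c("2022-Q1", "2022-Q3"), seed = 42)

a <- assess_facility(filter(forms, facility_id == "siteB",
                            period == "2022-Q1"), instr)
a
#> <pwat_assessment siteB 2022-Q1>
#>   overall: 57.2%  relative total: 343.6 / 600  (5 rooms, 3 interviews)
#>   physical           60.5%
#>   behavioural        55.0%
#>   environmental      58.8%
#>   training           53.4%
#>   procedural         64.0%
#>   culture_of_care    52.0%
```

The facility's true quality was 0.55 on the 0–1 latent scale, and the
engine recovers an overall score in that neighbourhood: 57.2% of the
possible weighted points, with a relative category total of 343.6 out of
600. `glance(a)` returns those headline numbers as a one-row tibble
(including the applied single-housing penalty, 0.4 points here —
the average of the per-room capped reductions), and `tidy(a)` the full
per-scope breakdown.

Benchmarking averages the year's two assessments, and the reporting layer
turns results into goals:

```r
bm <- benchmark_year(list(a, assess_facility(
  filter(forms, facility_id == "siteB", period == "2022-Q3"), instr)))
bm
#> <pwat_benchmark siteB 2022: 2 assessment(s) [2022-Q1, 2022-Q3]>
#>   overall: 52.1%  relative total: 314.1 / 600

suggest_focus(a, instr)
#> # A tibble: 3 × 5
#>   subcategory    category        percentage possible gaps
#>   <chr>          <chr>                <dbl>    <dbl> <list>
#> 1 acclimation    training              30.8       26 <tibble [3 × 9]>
#> 2 feeling valued culture_of_care       37.5       24 <tibble [4 × 9]>
#> 3 restraint      procedural            44.2       24 <tibble [4 × 9]>
```

The three lowest-scoring subcategories — each with its descriptor-level
gap list, heaviest-impact first — are the suggested improvement goals.
`render_report(bm, "markdown", assessment = a, instrument = instr)`
assembles the full facility report; `autoplot(a)` draws the category bar
chart; `plan_campaign()` computes how many rooms (10% of occupied rooms,
clamped to 3–10) and interviews (3–6, by personnel count) the next
assessment needs; `cross_site_summary()` collates benchmarks across
facilities into the A, B, C,… anonymised comparison table.

A command-line front end over the same functions is included at
`inst/cli/pwat.R` (`validate`, `score`, `benchmark`, `report`, `plan`,
`simulate`).

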