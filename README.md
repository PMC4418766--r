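# activprofile

Multidimensional physical-activity profiles and traffic-light health-target
feedback from minute-level wearable energy-expenditure data.

## The problem

A single activity number misleads. A person can log plenty of vigorous
exercise yet spend most of the day sitting; another can be on their feet all
day without a single vigorous minute. Whole-body monitors that estimate
energy expenditure minute by minute make it possible to describe activity
across several dimensions at once — and to feed that profile back to the
wearer as personalised, colour-coded infographics that make the trade-offs
visible.

`activprofile` implements that pipeline for 7-day, midnight-aligned,
minute-epoch records of energy expenditure (kcal/min) with a wear flag, as
exported by arm-worn multi-sensor devices:

1. **Individual MET anchoring.** Basal metabolic rate (BMR, kcal/day) is
   estimated from sex, age band and weight with the Schofield equations;
   1 MET is defined as that individual's BMR, so for each worn minute
   MET = kcal/min ÷ (BMR/1440). Non-wear minutes (device removed for
   showering etc.) are imputed at exactly 1 MET to complete the 7 × 24 h
   record.
2. **Intensity classification.** Half-open MET bands: sedentary [0, 1.5),
   light [1.5, 3.0), moderate [3.0, 6.0), vigorous [6.0, 10.2), very
   vigorous [10.2, ∞).
3. **The five-dimension profile.**
   - *PAL* = (total weekly kcal / 7) / BMR — physical activity level;
   - *sedentary % of waking day* — sedentary minutes per day minus an
     assumed 480 min of sleep, as a percentage of the 960-min waking day
     (floored at 0), averaged over 7 days;
   - *daily moderate minutes* — single minutes in [3, 6) METs per day;
   - *weekly bout minutes* — minutes in sustained runs of > 3 METs lasting
     ≥ 10 consecutive minutes;
   - *weekly vigorous minutes* — minutes at ≥ 6 METs over the week.
4. **Traffic-light target scoring.** Each dimension is compared with a
   configurable target: green *hit* (target met), amber *near* (within 25%
   of the target, inclusive), red *missed* (more than 25% away). PAL is
   additionally banded into sedentary (< 1.70), moderately active
   (1.70–1.99) and highly active (≥ 2.00).
5. **Deterministic SVG infographics.** A magnitude-free status wheel,
   target-vs-attainment bars, a bubble sliding scale, minute-by-minute
   day/week patterns and time/energy-by-intensity summaries, assembled into
   a multi-page feedback booklet.

A synthetic-data module generates weeks with planted sleep, non-wear,
exercise-bout and ambient-activity structure and tallies their ground-truth
profile through an independent code path, so the whole pipeline is testable
without real participant data.

## Worked example

```r
library(activprofile)

p <- participant("P01", "male", 63, 82)
schofield_bmr(p$sex, p$age_years, p$weight_kg)
#> <basal_rate> 1548.0 kcal/day (1.0750 kcal/min)

# a "weekend exerciser" archetype: three vigorous sessions on an otherwise
# sedentary week
sim <- simulate_week(scenario_presets()$archetype_a)
profile <- build_profile(sim$week)
profile
#> <multidim_profile>
#>   Physical activity level:              1.20
#>   Sedentary time (% waking day):       94.99
#>   Moderate activity (min/day):         10.00
#>   Moderate-vigorous bouts (min/week):  101.00
#>   Vigorous activity (min/week):       101.00

score_profile(profile, example_target_set())
#> <target_attainment>
#>   Physical activity level                1.20 vs     1.70 (at least)  MISSED
#>   Sedentary time (% waking day)         94.99 vs    65.00 (at most)  MISSED
#>   Moderate activity (min/day)           10.00 vs    30.00 (at least)  MISSED
#>   Moderate-vigorous bouts (min/week)   101.00 vs   150.00 (at least)  MISSED
#>   Vigorous activity (min/week)         101.00 vs    75.00 (at least)  HIT
```

Despite 101 vigorous minutes (target hit, green), this person misses the
other four targets: their three weekly sessions cannot compensate for an
otherwise sedentary routine (PAL 1.20, 95% of the waking day sedentary).
That dissociation between dimensions is exactly what the multidimensional
feedback is designed to surface.

`render_wheel()`, `render_target_bars()` and `render_bubble_scale()` turn
the attainment into the three target infographics;
`cli_profile(csv, participant.yaml, targets.yaml, out_dir)` runs the whole
pipeline from files on disk and writes `report.json` plus a nine-page SVG
booklet.

Targets are configuration, not constants: `example_target_set()` ships
illustrative values (PAL ≥ 1.70, sedentary ≤ 65% of the waking day,
≥ 30 moderate min/day, ≥ 150 bout min/week, ≥ 75 vigorous min/week); supply
your own YAML for a different guideline framework.

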