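---
title: "Multidimensional activity profiles: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multidimensional activity profiles: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(activprofile)
```

This vignette records how the pipeline's quantities are defined, which
parameters matter and why their defaults are what they are, what the
synthetic-data generator does and does not emulate, and the design choices
made where the design was genuinely open.

## The measurement model

The input is a 7-day record of per-minute energy expenditure (kcal/min)
from a body-worn monitor, with a wear flag, starting at midnight: exactly
10,080 strictly consecutive minutes. The package treats the device's energy
estimate as given — re-deriving energy from raw sensor channels is out of
scope — and anchors everything to the wearer's basal metabolic rate.

**BMR and individual METs.** BMR comes from the Schofield sex- and
age-band-specific linear equations (kcal/day form; adult bands 18–29,
30–59, ≥ 60). One MET is defined as the wearer's own BMR, so for a worn
minute MET = kcal/min ÷ (BMR/1440). This individual anchoring differs from
the population convention (3.5 ml O₂·kg⁻¹·min⁻¹); all cut-points below are
on the individual scale. No diurnal BMR variation is modelled: the
per-minute rate is exactly the daily rate over 1440.

**Non-wear imputation.** Wearers remove the device for showering and
water-based activities. Each non-wear minute is assigned exactly the
per-minute BMR (1.0 MET), completing the 24-hour record. Imputation is
driven solely by the wear flag; the package deliberately does not infer
non-wear from energy patterns, because a flag is available in the canonical
input and pattern-based detection would add an error mode the downstream
dimensions cannot distinguish from behaviour.

**Intensity bands.** Sedentary < 1.5 METs, light 1.5–2.9, moderate 3.0–5.9,
vigorous 6.0–10.1, very vigorous ≥ 10.2. Printed this way the labels leave
the interior gaps (2.9–3.0, 5.9–6.0, 10.1–10.2) undefined for continuous
MET values, so the bands are implemented as the only consistent continuous
partition: half-open intervals [0, 1.5), [1.5, 3), [3, 6), [6, 10.2),
[10.2, ∞). A value exactly on a cut-point falls in the upper band.

## The five dimensions

| dimension | definition | units |
|---|---|---|
| PAL | (total weekly kcal / 7) / BMR | — |
| sedentary % waking day | per day: max(0, sedentary min − 480) / 960 × 100, averaged over 7 days | % |
| daily moderate minutes | minutes with MET ∈ [3, 6) / 7 | min/day |
| weekly bout minutes | minutes in maximal runs of MET > 3 lasting ≥ 10 min | min/week |
| weekly vigorous minutes | minutes with MET ≥ 6 | min/week |

Notes on deliberate asymmetries:

- **Bout threshold is strict (> 3), band threshold inclusive (≥ 3).** The
  bout rule is worded as "greater than 3 METs" while the moderate band
  starts at 3.0; each is implemented exactly as worded. A minute at exactly
  3.0 METs therefore counts as a moderate single minute but never toward a
  bout.
- **Weekly vigorous uses ≥ 6.0 and is unbounded above**, so very-vigorous
  minutes count toward it. The source wordings disagree at the boundary
  ("> 6" vs a band starting at 6.0); the band convention was chosen so the
  dimension equals vigorous + very-vigorous minutes exactly.
- **Single moderate minutes count regardless of bout membership** — the
  moderate dimension and the bout dimension intentionally overlap.
- **Sleep subtraction floors at zero.** A day with under 480 sedentary
  minutes contributes 0%, not a negative percentage. Sleep itself is not
  detected; worn sleep minutes enter at their recorded energy, and only the
  sedentary dimension applies the fixed 8-hour assumption.
- **Bouts may cross midnight but not the week boundary**; days are
  calendar days, midnight to midnight.
- Bout contiguity is strict by default; `detect_bouts(tolerance = k)`
  exposes a drop-tolerance (absorb interior sub-threshold runs of ≤ k
  minutes, counting them toward the bout span) for sensitivity analyses
  only — the default of 0 is the definition.

## Target scoring

Each dimension has a positive target and a direction: `at_least` for the
four movement dimensions, `at_most` for the sedentary dimension (lower is
better; scoring it `at_least` would praise inactivity). Status is a pure
function of value, target and direction:

- `at_least`: hit if value ≥ target; near if 0.75·target ≤ value < target;
  missed below that.
- `at_most`: hit if value ≤ target; near if target < value ≤ 1.25·target;
  missed above that.

"Within 25%" is read as relative to the target and inclusive at the
boundary — "missed" is defined as *more than* 25% away, so exactly 25%
away is near. Relative attainment (value/target) is reported alongside the
status and drives the bar and bubble graphics.

The numeric targets are configuration, not package constants: appropriate
values belong to the guideline framework a study adopts. The shipped
example set (PAL 1.70, sedentary 65%, 30 moderate min/day, 150 bout
min/week, 75 vigorous min/week) combines widely used weekly
moderate-vigorous and vigorous activity reference points with round values
for the remaining dimensions, and exists so that examples, presets and
tests have a concrete, documented set to score against.

PAL is additionally banded into sedentary / moderately active / highly
active at 1.40–1.69 / 1.70–1.99 / 2.00–2.40. Printed to two decimals these
bands leave hairline gaps and open ends; they are implemented as contiguous
half-open intervals with clamping outside [1.40, 2.40], so 1.695 is
sedentary and 3.0 is highly active.

## Input format and validation

The canonical CSV dialect is strict: header `timestamp,energy_kcal,worn`,
ISO-8601 minute timestamps in naive local time, energy ≥ 0, `worn` in
{true, false}. Files must commence at midnight and span at most 7 days;
malformed rows, duplicates and out-of-window timestamps raise errors naming
the offending line. Minutes absent from the file are materialised as
non-wear records so the 10,080-minute grid always holds — grid completion
never alters energy values present in the file. Naive timestamps mean
daylight-saving transitions are not representable; weeks recorded across a
transition must be exported on a fixed clock, and the strict-consecutiveness
check rejects anything else. Vendor export formats vary; mapping them onto
the canonical dialect is an import-adapter concern kept outside the core.
Incomplete weeks (participants who stopped early) are rejected rather than
pro-rated: every dimension is defined on a full week, and pro-rating would
silently change the denominators.

## The synthetic-data generator

`simulate_week()` builds each day from state blocks: a sleep window
(default 23:00–07:00, intensity just below 1 MET), one non-wear block in
waking time, planted exercise bouts (log-normal duration, near-constant
MET), ambient moderate activity scattered as 1–8-minute runs, and a
sedentary/light baseline (uniform 1.0–1.4 METs with multiplicative
log-normal noise). A one-minute buffer around every planted
supra-threshold run prevents accidental merging, so planted bout minutes
are exactly the realised bout minutes. All randomness flows from the
scenario seed through an isolated RNG stream that does not disturb the
caller's.

The ground truth returned with each week is tallied from the realised
minutes by `tally_ground_truth()` — explicit per-day counting loops and a
linear run scan, sharing no code with the vectorised profiling path — so
"pipeline equals ground truth" is a genuine dual-route check, not a
tautology.

Two presets encode the dissociation archetypes used throughout the
examples: `archetype_a`, a "weekend exerciser" (three ~34-min vigorous
sessions, otherwise sedentary: vigorous hit, everything else short), and
`archetype_b`, a "busy mover" (~4 h/day of upper-moderate activity, high
PAL, no vigorous minutes, still a mostly sedentary remainder). Their
default parameters were chosen once, from the behavioural description of
each archetype, so that the planted margins are wide relative to simulator
noise; the scored status patterns are then stable across seeds.

What the generator does **not** emulate: autocorrelated real behaviour
(commuting rhythms, weekday/weekend structure), device estimation error,
partial wear days, or population heterogeneity. Passing tests therefore
demonstrate that the pipeline computes its definitions correctly on
realistic minute structure — not that the definitions are unbiased on any
particular device's real exports.

## Rendering

All graphics are SVG 1.1 assembled as plain text with fixed two-decimal
coordinate formatting and no timestamps or generated ids, so a fixed
(input, spec) pair renders byte-identically — reproducibility a wearer's
report can be audited against. Geometry (radii, bar lengths, canvas sizes)
is the package's own choice, held in `render_spec()` defaults; the three
status colours and five band colours must be pairwise distinct. Three
encoding rules are load-bearing:

- the **wheel** encodes status only — equal 72° segments, no magnitude, so
  equal statuses render identically whatever the values;
- **target bars** draw a unit-length reference bar and an attainment bar
  scaled by value/target, capped at 2× with an overflow marker;
- the **bubble scale** plots displacement (value/target − 1), sign-flipped
  for `at_most` dimensions so "better than target" is always the same side,
  clipped to ±1 target-multiple.

Every machine-checkable element carries a `data-dim` attribute, which is
how the tests verify colour-status agreement across all three target
graphics. The feedback booklet is three sections (patterns, summaries,
targets) × three variants = nine SVG pages plus a JSON manifest; variant
order can be shuffled with a recorded seed, for studies eliciting design
preferences in randomised order.

## Numerical choices

- PAL is computed as mean per-minute energy over per-minute BMR —
  algebraically identical to (weekly kcal/7)/BMR and exact (PAL = 1.0 to
  the last bit) for constant and fully imputed weeks.
- Imputed minutes are *set* to 1.0 MET rather than recomputed by division,
  so the identity is exact rather than within rounding.
- Report JSON and ground-truth JSON are written with 17 significant digits
  and round-trip IEEE doubles losslessly.
- Minute counts are tallied as integers; the only floating dimensions are
  PAL, the sedentary percentage and moderate minutes/day (an integer
  over 7).
- Boundary behaviour everywhere is resolved by explicit half-open/inclusive
  conventions (bands, bouts, traffic lights, PAL bands) and each boundary
  is pinned by a test.

## Problem sizes used in the checks

The bout-detection equivalence property runs 1,000 random 10,080-minute
weeks against an exhaustive scan oracle (seconds of runtime); conservation
checks run on 12–20 simulated weeks spanning the scenario grid; renderer
consistency samples 100 random attainments. These sizes give every
discrete code path (runs at boundaries, empty bout sets, capped bars,
clipped bubbles) many chances to appear while keeping the default suite
fast.

## Known limitations

- Epoch length is fixed at one minute; other epochs are out of scope.
- The Schofield adult bands start at 18; younger participants are rejected.
- Sedentary time is a MET threshold on 1-minute epochs, not a posture
  measure; sit/stand misclassification inherent to energy-only sensing is
  inherited from the device.
- The example targets are illustrative; the package takes no position on
  what the correct public-health targets are.
- Booklet output is SVG pages plus a manifest; PDF assembly is left to
  external tooling.
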