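Package: activprofile
Title: Multidimensional Physical-Activity Profiles and Traffic-Light
    Feedback from Minute-Level Wearable Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts minute-by-minute wearable energy-expenditure records
    into a five-dimension physical-activity profile (physical activity
    level, sedentary percentage of the waking day, daily moderate minutes,
    weekly moderate-vigorous bout minutes, weekly vigorous minutes),
    anchored to an individual basal metabolic rate estimated with the
    Schofield equations.  Non-wear minutes are imputed at basal rate,
    minutes are classified with MET cut-points, and sustained
    moderate-vigorous bouts are detected.  Each dimension is scored
    against a configurable health target with a traffic-light rule
    (hit/near/missed) and rendered as deterministic SVG infographics:
    a colour-coded wheel, target bars, a bubble scale, minute-by-minute
    day and week patterns, and time/energy-by-intensity summaries,
    assembled into a personalised feedback booklet.  A synthetic-data
    generator plants known activity structure so the whole pipeline is
    testable against exact ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
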