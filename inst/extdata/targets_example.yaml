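# Example multidimensional health-target set.
#
# Illustrative values assembled from widely used public-health reference
# points (150 weekly minutes of sustained moderate-vigorous activity, 75
# weekly vigorous minutes, 30 daily moderate minutes, PAL 1.70, at most 65%
# of the waking day sedentary).  Studies should replace these with the
# target values of their chosen guideline framework.
pal:
  target: 1.70
  direction: at_least
  label: "Physical activity level"
sedentary_pct_waking:
  target: 65
  direction: at_most
  label: "Sedentary time (% waking day)"
daily_moderate_min:
  target: 30
  direction: at_least
  label: "Moderate activity (min/day)"
weekly_bout_min:
  target: 150
  direction: at_least
  label: "Moderate-vigorous bouts (min/week)"
weekly_vigorous_min:
  target: 75
  direction: at_least
  label: "Vigorous activity (min/week)"
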