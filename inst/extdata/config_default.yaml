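# Default analysis configuration.
#
# Intensity bands are half-open on the individually anchored MET scale
# (1 MET = the wearer's Schofield-estimated basal metabolic rate):
#   sedentary [0, 1.5), light [1.5, 3.0), moderate [3.0, 6.0),
#   vigorous [6.0, 10.2), very vigorous [10.2, Inf).
thresholds:
  sedentary_lt: 1.5
  light_lt: 3.0
  moderate_lt: 6.0
  vigorous_lt: 10.2

# Sustained-bout rule: maximal runs of minutes strictly above threshold_met,
# at least min_duration minutes long; tolerance sub-threshold minutes may be
# absorbed inside a bout (0 = strict contiguity).
bout:
  threshold_met: 3.0
  min_duration: 10
  tolerance: 0

# Nightly sleep (minutes) assumed sedentary and subtracted before the
# sedentary percentage of the 16-hour waking day is computed.
sleep_min: 480
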