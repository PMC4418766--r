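# Fixture builders shared across the suite. Weeks are built directly from
# MET vectors (energy = MET x per-minute BMR) so expected dimension values
# are known by construction.

WEEK_START <- as.POSIXct("2015-03-02 00:00", tz = "UTC")  # a Monday

fix_participant <- function() participant("P01", "male", 63, 82)

fix_bmr <- function(p = fix_participant()) {
  schofield_bmr(p$sex, p$age_years, p$weight_kg)
}

# activity week from a MET vector; worn everywhere unless stated
met_week <- function(met, p = fix_participant(), worn = TRUE,
                     imputed = FALSE) {
  stopifnot(length(met) == 10080L)
  bmr <- fix_bmr(p)
  worn <- rep_len(worn, 10080L)
  energy <- met * bmr$bmr_kcal_min
  energy[!worn] <- 0
  activity_week(
    p,
    data.frame(timestamp = WEEK_START + 60 * (0:10079),
               energy_kcal = energy, worn = worn, imputed = FALSE),
    imputed = imputed
  )
}

flat_week <- function(met_value = 1, ...) met_week(rep(met_value, 10080L), ...)

# random MET series with realistic run structure: blocky state changes with
# occasional values exactly on the cut-points, to exercise the boundaries
random_met_series <- function(n = 10080L) {
  states <- c(0.9, 1.2, 1.5, 2, 3, 3.5, 5, 6, 7, 10.2, 11)
  n_runs <- ceiling(n / 2)
  lens <- sample(c(1:6, 8:15), n_runs, replace = TRUE)
  vals <- sample(states, n_runs, replace = TRUE)
  rep(vals, lens)[seq_len(n)]
}

# exhaustive run-length scan: the bout oracle used by the property and
# acceptance tests, independent of detect_bouts()'s rle path
scan_bouts_oracle <- function(met, threshold = 3, min_duration = 10) {
  starts <- integer(0); durs <- integer(0)
  run <- 0L
  for (i in seq_along(met)) {
    if (met[i] > threshold) {
      run <- run + 1L
    } else if (run > 0L) {
      if (run >= min_duration) {
        starts <- c(starts, i - run); durs <- c(durs, run)
      }
      run <- 0L
    }
  }
  if (run >= min_duration) {
    starts <- c(starts, length(met) - run + 1L); durs <- c(durs, run)
  }
  data.frame(start = starts, duration_min = durs)
}

# minimal valid CSV lines for a full week at constant energy
csv_week_lines <- function(energy = 1.075, worn = "true") {
  ts <- format(WEEK_START + 60 * (0:10079), "%Y-%m-%dT%H:%M")
  c("timestamp,energy_kcal,worn",
    sprintf("%s,%s,%s", ts, format(energy, digits = 10), worn))
}

random_attainment <- function() {
  values <- c(runif(1, 0.5, 2.5), runif(1, 20, 100), runif(1, 0, 300),
              runif(1, 0, 600), runif(1, 0, 300))
  profile <- structure(as.list(setNames(values, PROFILE_DIMENSIONS_T())),
                       class = "multidim_profile")
  score_profile(profile, example_target_set())
}

PROFILE_DIMENSIONS_T <- function() {
  c("pal", "sedentary_pct_waking", "daily_moderate_min",
    "weekly_bout_min", "weekly_vigorous_min")
}
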