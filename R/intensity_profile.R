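#' MET cut-points for intensity classification
#'
#' The minute bands are half-open intervals on the individually anchored MET
#' scale: sedentary [0, 1.5), light [1.5, 3.0), moderate [3.0, 6.0),
#' vigorous [6.0, 10.2), very vigorous [10.2, Inf). The printed band labels
#' in the accelerometry literature ("1.5-2.9", "3.0-5.9", "6.0-10.1") leave
#' the interior gaps undefined for continuous METs; half-open upper bounds at
#' 3.0, 6.0 and 10.2 are the only continuous partition consistent with those
#' endpoints.
#'
#' @param sedentary_lt Upper bound (exclusive) of the sedentary band; METs.
#' @param light_lt Upper bound (exclusive) of the light band.
#' @param moderate_lt Upper bound (exclusive) of the moderate band.
#' @param vigorous_lt Upper bound (exclusive) of the vigorous band.
#' @return An object of class `intensity_thresholds`.
#' @export
intensity_thresholds <- function(sedentary_lt = 1.5, light_lt = 3.0,
                                 moderate_lt = 6.0, vigorous_lt = 10.2) {
  cuts <- c(sedentary_lt, light_lt, moderate_lt, vigorous_lt)
  if (any(!is.finite(cuts)) || any(cuts <= 0) || any(diff(cuts) <= 0)) {
    stop("intensity thresholds must be positive and strictly increasing",
         call. = FALSE)
  }
  structure(
    list(sedentary_lt = sedentary_lt, light_lt = light_lt,
         moderate_lt = moderate_lt, vigorous_lt = vigorous_lt),
    class = "intensity_thresholds"
  )
}

#' @export
print.intensity_thresholds <- function(x, ...) {
  cat(sprintf(
    "<intensity_thresholds> sed<%.1f | light<%.1f | mod<%.1f | vig<%.1f | very>=%.1f METs\n",
    x$sedentary_lt, x$light_lt, x$moderate_lt, x$vigorous_lt, x$vigorous_lt))
  invisible(x)
}

#' Classify MET values into intensity bands
#'
#' Vectorised over `met`. Bands are the half-open intervals of
#' [intensity_thresholds()]; a value exactly on a cut-point falls in the
#' upper band (e.g. 3.0 METs is moderate, 10.2 METs is very vigorous).
#'
#' @param met Numeric vector of MET values, all >= 0.
#' @param thresholds An [intensity_thresholds] object.
#' @return A factor with levels `sedentary`, `light`, `moderate`,
#'   `vigorous`, `very_vigorous`.
#' @export
#' @examples
#' classify_minute(c(1.4, 1.5, 3.0, 6.0, 10.2), intensity_thresholds())
classify_minute <- function(met, thresholds = intensity_thresholds()) {
  if (any(!is.finite(met)) || any(met < 0)) {
    stop("MET values must be finite and non-negative", call. = FALSE)
  }
  cut(met,
      breaks = c(0, thresholds$sedentary_lt, thresholds$light_lt,
                 thresholds$moderate_lt, thresholds$vigorous_lt, Inf),
      labels = INTENSITY_BANDS,
      right = FALSE, include.lowest = TRUE)
}

#' Time and energy spent in each intensity band
#'
#' Tallies minutes and kcal per band over the imputed week. Minutes always
#' sum to 10,080 and kcal to the total weekly energy expenditure.
#'
#' @param week An imputed [activity_week].
#' @param bmr A [schofield_bmr()] result.
#' @param thresholds An [intensity_thresholds] object.
#' @return A data frame with columns `band`, `minutes`, `kcal` (five rows,
#'   band order sedentary to very vigorous).
#' @export
time_and_energy_by_band <- function(week, bmr,
                                    thresholds = intensity_thresholds()) {
  met <- met_series(week, bmr)
  band <- classify_minute(met, thresholds)
  energy <- week$records$energy_kcal
  energy[!week$records$worn | week$records$imputed] <- bmr$bmr_kcal_min
  minutes <- as.integer(tabulate(band, nbins = 5L))
  kcal <- vapply(seq_along(INTENSITY_BANDS),
                 function(i) sum(energy[as.integer(band) == i]), numeric(1))
  data.frame(band = INTENSITY_BANDS, minutes = minutes, kcal = kcal)
}

#' Average daily single minutes of moderate activity
#'
#' Counts every minute with MET in [3, 6) -- single minutes count regardless
#' of whether they sit inside a sustained bout -- and divides by 7.
#'
#' @inheritParams time_and_energy_by_band
#' @return Minutes per day (real).
#' @export
daily_moderate_minutes <- function(week, bmr,
                                   thresholds = intensity_thresholds()) {
  met <- met_series(week, bmr)
  sum(met >= thresholds$light_lt & met < thresholds$moderate_lt) / 7
}

#' Detect sustained moderate-vigorous bouts
#'
#' A bout is a maximal run of consecutive minutes with MET strictly greater
#' than `threshold_met` lasting at least `min_duration` minutes. The strict
#' ">" follows the bout definition ("all activity greater than 3 METs"),
#' which differs deliberately from the moderate band's inclusive ">= 3.0".
#' Bouts may cross midnight but not the week boundary. `tolerance` allows up
#' to that many consecutive sub-threshold minutes inside a bout without
#' breaking it (default 0: strict contiguity); tolerated gap minutes count
#' toward the bout duration.
#'
#' @param week An imputed [activity_week].
#' @param bmr A [schofield_bmr()] result.
#' @param threshold_met Bout intensity threshold in METs (strict lower
#'   bound); default 3.
#' @param min_duration Minimum bout length in minutes; default 10.
#' @param tolerance Maximum run of sub-threshold minutes absorbed inside a
#'   bout; default 0.
#' @return A data frame with columns `start` (1-based minute index of the
#'   week), `duration_min`, `mean_met` (mean MET over the bout span).
#' @export
detect_bouts <- function(week, bmr, threshold_met = 3, min_duration = 10,
                         tolerance = 0) {
  met <- met_series(week, bmr)
  above <- met > threshold_met
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts, end = ends, above = r$values)

  if (tolerance > 0 && any(runs$above)) {
    # absorb interior sub-threshold runs no longer than `tolerance`;
    # leading/trailing gaps never merge outward
    len <- runs$end - runs$start + 1L
    interior <- seq_len(nrow(runs)) > 1L & seq_len(nrow(runs)) < nrow(runs)
    absorb <- !runs$above & interior & len <= tolerance
    grp <- cumsum(!runs$above & !absorb)  # increments at every breaking gap
    above_grp <- grp[runs$above]
    runs <- data.frame(
      start = as.integer(tapply(runs$start[runs$above], above_grp, min)),
      end = as.integer(tapply(runs$end[runs$above], above_grp, max))
    )
  } else {
    runs <- runs[runs$above, c("start", "end"), drop = FALSE]
  }

  dur <- runs$end - runs$start + 1L
  keep <- dur >= min_duration
  runs <- runs[keep, , drop = FALSE]
  dur <- dur[keep]
  data.frame(
    start = as.integer(runs$start),
    duration_min = as.integer(dur),
    mean_met = vapply(seq_len(nrow(runs)),
                      function(i) mean(met[runs$start[i]:runs$end[i]]),
                      numeric(1))
  )
}

#' Total weekly minutes in sustained bouts
#'
#' @param bouts A [detect_bouts()] result.
#' @return Sum of bout durations, minutes per week.
#' @export
weekly_bout_minutes <- function(bouts) {
  if (nrow(bouts) == 0L) return(0)
  as.numeric(sum(bouts$duration_min))
}

#' Total weekly minutes of vigorous activity
#'
#' Counts every minute at or above the vigorous cut-point (default 6.0
#' METs), including very vigorous minutes, accumulated over the whole week.
#' The bout-footnote wording ">6 METs" and the band table's "6.0-10.1" are
#' inconsistent at the boundary; the band convention (>= 6.0, unbounded
#' above) is used so the dimension equals vigorous + very vigorous minutes.
#'
#' @inheritParams time_and_energy_by_band
#' @return Minutes per week (integer-valued).
#' @export
weekly_vigorous_minutes <- function(week, bmr,
                                    thresholds = intensity_thresholds()) {
  met <- met_series(week, bmr)
  as.numeric(sum(met >= thresholds$moderate_lt))
}

#' Sedentary time as a percentage of the 16-hour waking day
#'
#' For each calendar day, 8 hours (480 min) of sleep are assumed sedentary
#' and subtracted from the day's total sedentary minutes (< 1.5 METs); the
#' remainder is expressed as a percentage of the 16-hour (960 min) waking
#' day, floored at 0 so a day with under 480 sedentary minutes contributes
#' 0% rather than a negative value. The seven daily percentages are
#' averaged.
#'
#' @inheritParams time_and_energy_by_band
#' @param sleep_min Assumed nightly sleep in minutes; default 480.
#' @return Percentage in [0, 100].
#' @export
sedentary_waking_pct <- function(week, bmr,
                                 thresholds = intensity_thresholds(),
                                 sleep_min = 480) {
  met <- met_series(week, bmr)
  sedentary <- met < thresholds$sedentary_lt
  per_day <- matrix(sedentary, nrow = 7L, ncol = MINUTES_PER_DAY, byrow = TRUE)
  day_min <- rowSums(per_day)
  waking <- MINUTES_PER_DAY - sleep_min
  mean(pmax(0, day_min - sleep_min) / waking * 100)
}

#' Build the five-dimension activity profile
#'
#' Composes the dimension operations: PAL, sedentary percentage of the
#' waking day, daily moderate single minutes, weekly sustained-bout minutes,
#' and weekly vigorous minutes. The participant's BMR is estimated with the
#' Schofield equations and non-wear minutes are imputed at basal rate if the
#' week has not been imputed yet.
#'
#' @param week An [activity_week].
#' @param participant A [participant]; defaults to the week's own.
#' @param thresholds An [intensity_thresholds] object.
#' @param sleep_min Assumed nightly sleep minutes for the sedentary
#'   dimension; default 480.
#' @param bout_threshold_met Strict MET threshold for bout membership;
#'   default 3.
#' @param bout_min_duration Minimum bout duration in minutes; default 10.
#' @param bout_tolerance Sub-threshold minutes absorbed inside a bout;
#'   default 0.
#' @return An object of class `multidim_profile` with fields `pal`,
#'   `sedentary_pct_waking`, `daily_moderate_min`, `weekly_bout_min`,
#'   `weekly_vigorous_min`.
#' @export
build_profile <- function(week, participant = week$participant,
                          thresholds = intensity_thresholds(),
                          sleep_min = 480,
                          bout_threshold_met = 3,
                          bout_min_duration = 10,
                          bout_tolerance = 0) {
  stopifnot(inherits(week, "activity_week"))
  bmr <- schofield_bmr(participant$sex, participant$age_years,
                       participant$weight_kg)
  if (!week_is_imputed(week)) week <- impute_nonwear(week, bmr)
  bouts <- detect_bouts(week, bmr, threshold_met = bout_threshold_met,
                        min_duration = bout_min_duration,
                        tolerance = bout_tolerance)
  structure(
    list(
      pal = compute_pal(week, bmr),
      sedentary_pct_waking = sedentary_waking_pct(week, bmr, thresholds,
                                                  sleep_min),
      daily_moderate_min = daily_moderate_minutes(week, bmr, thresholds),
      weekly_bout_min = weekly_bout_minutes(bouts),
      weekly_vigorous_min = weekly_vigorous_minutes(week, bmr, thresholds)
    ),
    participant = participant,
    bmr = bmr,
    thresholds = thresholds,
    class = "multidim_profile"
  )
}

#' @export
print.multidim_profile <- function(x, ...) {
  cat("<multidim_profile>\n")
  cat(sprintf("  %-34s %7.2f\n", paste0(PROFILE_DIMENSION_LABELS, ":"),
              unlist(x[PROFILE_DIMENSIONS])), sep = "")
  invisible(x)
}
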