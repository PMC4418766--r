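#' Schofield BMR coefficients (kcal/day form)
#'
#' The published Schofield age-band and sex specific linear-in-weight
#' equations for predicting basal metabolic rate, in the kcal/day form
#' (Schofield, Hum Nutr Clin Nutr 1985;39 Suppl 1:5-41). Adult bands only:
#' 18--29, 30--59 and >= 60 years. BMR (kcal/day) = slope x weight (kg) +
#' intercept.
#'
#' @return A data frame with columns `sex`, `age_min`, `age_max`, `slope`,
#'   `intercept`.
#' @export
schofield_coefficients <- function() {
  data.frame(
    sex       = rep(c("male", "female"), each = 3L),
    age_min   = rep(c(18L, 30L, 60L), 2L),
    age_max   = rep(c(29L, 59L, 110L), 2L),
    slope     = c(15.057, 11.472, 11.711, 14.818, 8.126, 9.082),
    intercept = c(692.2, 873.1, 587.7, 486.6, 845.6, 658.5)
  )
}

#' Estimate basal metabolic rate with the Schofield equations
#'
#' Basal metabolic rate (BMR) anchors the individual MET scale: 1 MET is
#' defined as the participant's own BMR, so all intensity classification is
#' relative to this estimate. The per-minute rate is the daily rate divided
#' by 1440 (no diurnal variation is modelled).
#'
#' @param sex `"male"` or `"female"`.
#' @param age_years Integer age in years, >= 18 (younger ages use different
#'   published bands and are not supported).
#' @param weight_kg Body weight in kg.
#' @param coefficients Coefficient table in the layout of
#'   [schofield_coefficients()]; overridable for sensitivity analyses.
#'
#' @return An object of class `basal_rate` with fields `bmr_kcal_day` and
#'   `bmr_kcal_min` (`= bmr_kcal_day / 1440`).
#' @export
#' @examples
#' schofield_bmr("male", 63, 82)  # 11.711 * 82 + 587.7 = 1548.0 kcal/day
schofield_bmr <- function(sex, age_years, weight_kg,
                          coefficients = schofield_coefficients()) {
  sex <- match.arg(sex, c("male", "female"))
  age_years <- as.integer(age_years)
  if (is.na(age_years) || age_years < 18L) {
    stop("unsupported Schofield age band: age ", age_years,
         " (adult bands start at 18 y)", call. = FALSE)
  }
  if (!is.finite(weight_kg) || weight_kg <= 0) {
    stop("weight_kg must be positive", call. = FALSE)
  }
  row <- coefficients[coefficients$sex == sex &
                      coefficients$age_min <= age_years &
                      coefficients$age_max >= age_years, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop("no unique Schofield band for sex=", sex, ", age=", age_years,
         call. = FALSE)
  }
  day <- row$slope * weight_kg + row$intercept
  structure(
    list(bmr_kcal_day = day, bmr_kcal_min = day / MINUTES_PER_DAY),
    class = "basal_rate"
  )
}

#' @export
print.basal_rate <- function(x, ...) {
  cat(sprintf("<basal_rate> %.1f kcal/day (%.4f kcal/min)\n",
              x$bmr_kcal_day, x$bmr_kcal_min))
  invisible(x)
}

#' Convert an activity week to a per-minute MET series
#'
#' METs are individually anchored: for a worn minute,
#' MET = energy_kcal / bmr_kcal_min. Non-wear and imputed minutes are 1.0
#' MET exactly (device-off time is assumed spent at basal rate).
#'
#' @param week An [activity_week].
#' @param bmr A [schofield_bmr()] result.
#' @return A numeric vector of 10,080 MET values.
#' @export
met_series <- function(week, bmr) {
  stopifnot(inherits(week, "activity_week"), inherits(bmr, "basal_rate"))
  r <- week$records
  met <- r$energy_kcal / bmr$bmr_kcal_min
  met[!r$worn | r$imputed] <- 1.0
  met
}

#' Impute non-wear minutes at basal rate
#'
#' Completes the 7-day, 24-hour record: every minute with `worn = FALSE` has
#' its energy set to the participant's per-minute BMR and is flagged
#' `imputed`. Worn minutes are untouched. The returned week is marked as
#' imputed, which downstream profile operations require.
#'
#' @param week An [activity_week].
#' @param bmr A [schofield_bmr()] result.
#' @return An imputed [activity_week].
#' @export
impute_nonwear <- function(week, bmr) {
  stopifnot(inherits(week, "activity_week"), inherits(bmr, "basal_rate"))
  r <- week$records
  nw <- !r$worn
  r$energy_kcal[nw] <- bmr$bmr_kcal_min
  r$imputed[nw] <- TRUE
  activity_week(week$participant, r, imputed = TRUE)
}

#' Physical activity level (PAL) of a week
#'
#' PAL = average total daily energy expenditure / basal metabolic rate,
#' i.e. (total weekly kcal / 7) / bmr_kcal_day. The week must already be
#' imputed so that the energy total covers all 10,080 minutes.
#'
#' @param week An imputed [activity_week].
#' @param bmr A [schofield_bmr()] result.
#' @return PAL as a positive scalar.
#' @export
compute_pal <- function(week, bmr) {
  stopifnot(inherits(week, "activity_week"), inherits(bmr, "basal_rate"))
  if (!week_is_imputed(week) && any(!week$records$worn)) {
    stop("week has non-wear minutes; call impute_nonwear() before ",
         "compute_pal()", call. = FALSE)
  }
  # (total kcal / 7) / bmr_kcal_day, computed as mean per-minute energy over
  # per-minute BMR: algebraically identical and exact for constant weeks
  mean(week$records$energy_kcal) / bmr$bmr_kcal_min
}
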