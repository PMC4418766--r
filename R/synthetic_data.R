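# State-block week generator: each day is laid out as sleep, one non-wear
# block, planted exercise bouts, scattered ambient moderate runs, and a
# sedentary/light baseline. Simple by design -- the point is exact, known
# ground truth for every planted feature, not behavioural realism.

#' Define a synthetic activity-week scenario
#'
#' A scenario fixes the generative parameters for one simulated 7-day week:
#' the sleep window, the number/duration/intensity of planted exercise
#' bouts, the daily amount of scattered ("ambient") moderate activity in
#' short sub-bout runs, daily non-wear time, and the noise of the
#' sedentary/light baseline. All randomness flows from the single `seed`.
#'
#' @param seed Integer RNG seed (mandatory; the week is reproducible).
#' @param participant A [participant]; defaults to a 63-year-old, 82 kg
#'   male, a typical middle-aged cohort member.
#' @param sleep_start,sleep_end Daily sleep window as `"HH:MM"` strings;
#'   default 23:00--07:00 (8 h, matching the sedentary-dimension sleep
#'   assumption). Sleep minutes are generated just below basal-equivalent
#'   intensity.
#' @param n_exercise_bouts_per_week Number of planted sustained exercise
#'   bouts, placed on distinct random days.
#' @param bout_duration_meanlog,bout_duration_sdlog Log-normal parameters of
#'   bout duration in minutes (durations are rounded and floored at 10).
#' @param bout_met_mean,bout_met_sd Per-minute bout intensity, normal,
#'   truncated to 3 standard deviations around the mean (and never below
#'   3.05 METs).
#' @param ambient_moderate_min_per_day Minutes per day of moderate activity
#'   scattered as 1--8 minute runs, too short to form bouts.
#' @param ambient_met_range Uniform range of ambient moderate intensity;
#'   must lie inside the moderate band \[3, 6).
#' @param nonwear_min_per_day Length of the single daily non-wear block
#'   (device off, e.g. showering), placed in waking time.
#' @param baseline_met_noise SD of multiplicative log-normal noise on the
#'   baseline sedentary/light mixture (uniform 1.0--1.4 METs).
#' @return An object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(seed,
                               participant = activprofile::participant(
                                 "SIM", "male", 63, 82),
                               sleep_start = "23:00", sleep_end = "07:00",
                               n_exercise_bouts_per_week = 3L,
                               bout_duration_meanlog = log(34),
                               bout_duration_sdlog = 0.08,
                               bout_met_mean = 7.5, bout_met_sd = 0.3,
                               ambient_moderate_min_per_day = 20L,
                               ambient_met_range = c(3.2, 5.8),
                               nonwear_min_per_day = 30L,
                               baseline_met_noise = 0.08) {
  stopifnot(inherits(participant, "participant"),
            is.finite(seed), n_exercise_bouts_per_week >= 0,
            ambient_moderate_min_per_day >= 0, nonwear_min_per_day >= 0,
            baseline_met_noise >= 0,
            length(ambient_met_range) == 2L,
            ambient_met_range[1] >= 3, ambient_met_range[2] < 6,
            ambient_met_range[1] < ambient_met_range[2])
  sleep_len <- local({
    s <- hm_to_minute(sleep_start); e <- hm_to_minute(sleep_end)
    (e - s) %% MINUTES_PER_DAY
  })
  # worst-case single-day load: sleep + non-wear + ambient + one long bout
  worst_bout <- if (n_exercise_bouts_per_week > 0) {
    ceiling(exp(bout_duration_meanlog + 4 * bout_duration_sdlog))
  } else 0
  load <- sleep_len + nonwear_min_per_day + ambient_moderate_min_per_day +
    worst_bout
  if (load > MINUTES_PER_DAY) {
    stop("infeasible scenario: requested minutes (", load,
         ") exceed the 1440-minute day", call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), participant = participant,
         sleep_start = sleep_start, sleep_end = sleep_end,
         n_exercise_bouts_per_week = as.integer(n_exercise_bouts_per_week),
         bout_duration_meanlog = bout_duration_meanlog,
         bout_duration_sdlog = bout_duration_sdlog,
         bout_met_mean = bout_met_mean, bout_met_sd = bout_met_sd,
         ambient_moderate_min_per_day = as.integer(ambient_moderate_min_per_day),
         ambient_met_range = ambient_met_range,
         nonwear_min_per_day = as.integer(nonwear_min_per_day),
         baseline_met_noise = baseline_met_noise),
    class = "synthetic_scenario"
  )
}

hm_to_minute <- function(hm) {
  p <- as.integer(strsplit(hm, ":", fixed = TRUE)[[1L]])
  p[1L] * 60L + p[2L]
}

# mark span `s..e` with `type`, plus a 1-minute buffer either side (buffers
# stay baseline but are unavailable for later placements, so planted
# supra-threshold runs can never merge)
mark_span <- function(type_vec, s, e, type, lo, hi) {
  type_vec[s:e] <- type
  if (s - 1L >= lo && type_vec[s - 1L] == "free") type_vec[s - 1L] <- "buffer"
  if (e + 1L <= hi && type_vec[e + 1L] == "free") type_vec[e + 1L] <- "buffer"
  type_vec
}

# random start of a fully-"free" span of `len` minutes within [lo, hi]
pick_free_start <- function(type_vec, lo, hi, len) {
  free <- type_vec[lo:hi] == "free"
  r <- rle(free)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$values & r$lengths >= len
  if (!any(ok)) return(NA_integer_)
  nstart <- r$lengths[ok] - len + 1L
  run <- sample.int(sum(ok), 1L, prob = nstart)
  s_rel <- starts[ok][run] + sample.int(nstart[run], 1L) - 1L
  lo + s_rel - 1L
}

#' Simulate a 7-day activity week with known ground truth
#'
#' Generates a midnight-aligned [activity_week] from a
#' [synthetic_scenario] and, alongside it, the five-dimension ground-truth
#' profile tallied directly from the realised minute series by
#' [tally_ground_truth()] -- a deliberately plain second implementation of
#' the dimension definitions, so the pipeline can be checked against it
#' end to end.
#'
#' @param scenario A [synthetic_scenario].
#' @return A list with elements `week` (an [activity_week], non-wear minutes
#'   unimputed), `truth` (a `multidim_profile`) and `participant`.
#' @export
simulate_week <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(scenario$seed)

  p <- scenario$participant
  bmr <- schofield_bmr(p$sex, p$age_years, p$weight_kg)
  n <- MINUTES_PER_WEEK
  met <- numeric(n)
  type <- rep("free", n)

  ss <- hm_to_minute(scenario$sleep_start)
  se <- hm_to_minute(scenario$sleep_end)
  for (d in 0:6) {
    base <- d * MINUTES_PER_DAY
    sleep_idx <- if (ss > se) {
      c(base + seq.int(ss, MINUTES_PER_DAY - 1L), base + seq.int(0L, se - 1L))
    } else {
      base + seq.int(ss, se - 1L)
    }
    sleep_idx <- sleep_idx + 1L
    type[sleep_idx] <- "sleep"
  }

  # one non-wear block per day, inside waking time
  if (scenario$nonwear_min_per_day > 0) {
    for (d in 0:6) {
      lo <- d * MINUTES_PER_DAY + 1L
      hi <- (d + 1L) * MINUTES_PER_DAY
      s <- pick_free_start(type, lo, hi, scenario$nonwear_min_per_day)
      if (is.na(s)) stop("infeasible scenario: no room for non-wear block",
                         call. = FALSE)
      type[s:(s + scenario$nonwear_min_per_day - 1L)] <- "nonwear"
    }
  }

  # planted exercise bouts on distinct random days
  nb <- scenario$n_exercise_bouts_per_week
  if (nb > 0) {
    days <- if (nb <= 7L) sample(0:6, nb) else sample(0:6, nb, replace = TRUE)
    for (d in days) {
      len <- max(10L, as.integer(round(stats::rlnorm(
        1L, scenario$bout_duration_meanlog, scenario$bout_duration_sdlog))))
      lo <- d * MINUTES_PER_DAY + 1L
      hi <- (d + 1L) * MINUTES_PER_DAY
      s <- pick_free_start(type, lo, hi, len)
      if (is.na(s)) stop("infeasible scenario: no room for exercise bout",
                         call. = FALSE)
      e <- s + len - 1L
      m <- stats::rnorm(len, scenario$bout_met_mean, scenario$bout_met_sd)
      m <- pmin(pmax(m, max(3.05, scenario$bout_met_mean -
                              3 * scenario$bout_met_sd)),
                scenario$bout_met_mean + 3 * scenario$bout_met_sd)
      met[s:e] <- m
      type <- mark_span(type, s, e, "bout", lo, hi)
    }
  }

  # ambient moderate activity: short runs, never long enough to be a bout
  if (scenario$ambient_moderate_min_per_day > 0) {
    for (d in 0:6) {
      lo <- d * MINUTES_PER_DAY + 1L
      hi <- (d + 1L) * MINUTES_PER_DAY
      placed <- 0L
      while (placed < scenario$ambient_moderate_min_per_day) {
        len <- min(sample(3:8, 1L),
                   scenario$ambient_moderate_min_per_day - placed)
        s <- pick_free_start(type, lo, hi, len)
        if (is.na(s)) stop("infeasible scenario: no room for ambient ",
                           "moderate activity", call. = FALSE)
        e <- s + len - 1L
        met[s:e] <- stats::runif(len, scenario$ambient_met_range[1],
                                 scenario$ambient_met_range[2])
        type <- mark_span(type, s, e, "moderate", lo, hi)
        placed <- placed + len
      }
    }
  }

  sleep_n <- sum(type == "sleep")
  met[type == "sleep"] <- pmin(pmax(
    0.95 * exp(stats::rnorm(sleep_n, 0, 0.04)), 0.8), 1.3)
  base_idx <- type %in% c("free", "buffer")
  met[base_idx] <- pmin(pmax(
    stats::runif(sum(base_idx), 1.0, 1.4) *
      exp(stats::rnorm(sum(base_idx), 0, scenario$baseline_met_noise)),
    0.5), 2.9)

  worn <- type != "nonwear"
  energy <- met * bmr$bmr_kcal_min
  energy[!worn] <- 0

  start <- as.POSIXct("2015-03-02 00:00", tz = "UTC")  # a Monday
  week <- activity_week(
    p,
    data.frame(timestamp = start + 60 * (seq_len(n) - 1L),
               energy_kcal = energy, worn = worn, imputed = FALSE)
  )
  list(week = week,
       truth = tally_ground_truth(week, p),
       participant = p)
}

#' Tally the five dimensions by direct minute-by-minute scan
#'
#' A plain reference implementation of the dimension definitions, used as
#' the independent ground-truth tally for simulated weeks: minutes are
#' classified and counted in explicit per-day loops and bouts are found with
#' a linear run scan, with no code shared with the profiling operations
#' ([classify_minute()], [detect_bouts()] and friends). Non-wear minutes are
#' taken at 1 MET (the imputation rule) directly.
#'
#' @param week An [activity_week].
#' @param participant A [participant]; defaults to the week's own.
#' @param thresholds An [intensity_thresholds] object.
#' @param sleep_min Assumed nightly sleep minutes; default 480.
#' @param bout_threshold_met,bout_min_duration Bout rule; defaults 3 METs
#'   (strict) and 10 minutes.
#' @return A `multidim_profile`.
#' @export
tally_ground_truth <- function(week, participant = week$participant,
                               thresholds = intensity_thresholds(),
                               sleep_min = 480,
                               bout_threshold_met = 3,
                               bout_min_duration = 10) {
  bmr <- schofield_bmr(participant$sex, participant$age_years,
                       participant$weight_kg)
  r <- week$records
  met <- ifelse(r$worn & !r$imputed, r$energy_kcal / bmr$bmr_kcal_min, 1.0)
  energy <- ifelse(r$worn, r$energy_kcal, bmr$bmr_kcal_min)
  energy[r$imputed] <- bmr$bmr_kcal_min

  moderate <- 0L
  vigorous <- 0L
  sed_day <- integer(7)
  for (d in 1:7) {
    for (i in ((d - 1L) * MINUTES_PER_DAY + 1L):(d * MINUTES_PER_DAY)) {
      m <- met[i]
      if (m < thresholds$sedentary_lt) sed_day[d] <- sed_day[d] + 1L
      if (m >= thresholds$light_lt && m < thresholds$moderate_lt) {
        moderate <- moderate + 1L
      }
      if (m >= thresholds$moderate_lt) vigorous <- vigorous + 1L
    }
  }

  bout_min <- 0L
  run <- 0L
  for (i in seq_len(MINUTES_PER_WEEK)) {
    if (met[i] > bout_threshold_met) {
      run <- run + 1L
    } else {
      if (run >= bout_min_duration) bout_min <- bout_min + run
      run <- 0L
    }
  }
  if (run >= bout_min_duration) bout_min <- bout_min + run

  waking <- MINUTES_PER_DAY - sleep_min
  sed_pct <- mean(pmax(0, sed_day - sleep_min) / waking * 100)

  structure(
    list(pal = mean(energy) / bmr$bmr_kcal_min,
         sedentary_pct_waking = sed_pct,
         daily_moderate_min = moderate / 7,
         weekly_bout_min = as.numeric(bout_min),
         weekly_vigorous_min = as.numeric(vigorous)),
    participant = participant, bmr = bmr, thresholds = thresholds,
    class = "multidim_profile"
  )
}

#' Archetype scenario presets
#'
#' Two behavioural archetypes illustrating that the five dimensions can
#' dissociate within one person:
#' \describe{
#'   \item{archetype_a}{A "weekend exerciser": three ~34-minute vigorous
#'     sessions a week (vigorous target comfortably hit) on an otherwise
#'     sedentary routine, so PAL, sedentary time, daily moderate minutes and
#'     bout minutes all fall short of the example targets.}
#'   \item{archetype_b}{A "busy mover": around four daily hours on their
#'     feet with much upper-moderate activity and a high PAL, but no
#'     vigorous activity at all and still a mostly sedentary remainder of
#'     the day.}
#' }
#' Scored against [example_target_set()], archetype A hits only the vigorous
#' dimension; archetype B hits PAL and daily moderate minutes but not the
#' sedentary or vigorous dimensions.
#'
#' @param seed Optional base seed; each preset derives its own fixed offset
#'   from it. With the default `NULL`, the presets use their built-in seeds.
#' @return A named list of [synthetic_scenario] objects.
#' @export
scenario_presets <- function(seed = NULL) {
  sa <- if (is.null(seed)) 101L else as.integer(seed) + 11L
  sb <- if (is.null(seed)) 202L else as.integer(seed) + 22L
  list(
    archetype_a = synthetic_scenario(
      seed = sa,
      n_exercise_bouts_per_week = 3L,
      bout_duration_meanlog = log(34), bout_duration_sdlog = 0.08,
      bout_met_mean = 7.5, bout_met_sd = 0.3,
      ambient_moderate_min_per_day = 10L,
      ambient_met_range = c(3.2, 5.8),
      nonwear_min_per_day = 30L,
      baseline_met_noise = 0.08
    ),
    archetype_b = synthetic_scenario(
      seed = sb,
      n_exercise_bouts_per_week = 0L,
      ambient_moderate_min_per_day = 250L,
      ambient_met_range = c(4.2, 5.9),
      nonwear_min_per_day = 30L,
      baseline_met_noise = 0.08
    )
  )
}
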