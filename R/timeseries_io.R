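#' Participant metadata
#'
#' Holds the covariates needed to anchor energy expenditure to an individual
#' basal metabolic rate: sex, age and body weight (the Schofield covariates),
#' plus an opaque identifier.
#'
#' @param id Participant identifier (any non-empty string).
#' @param sex `"male"` or `"female"`.
#' @param age_years Integer age in years; 18--110.
#' @param weight_kg Body weight in kilograms; 30--250.
#'
#' @return An object of class `participant`.
#' @export
#' @examples
#' participant("P01", "male", 63, 82)
participant <- function(id, sex, age_years, weight_kg) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("participant id must be a non-empty string", call. = FALSE)
  }
  sex <- match.arg(sex, c("male", "female"))
  age_years <- as.integer(age_years)
  if (is.na(age_years) || age_years < 18L || age_years > 110L) {
    stop("age_years must be an integer in [18, 110], got ", age_years,
         call. = FALSE)
  }
  weight_kg <- as.numeric(weight_kg)
  if (!is.finite(weight_kg) || weight_kg < 30 || weight_kg > 250) {
    stop("weight_kg must be in [30, 250], got ", weight_kg, call. = FALSE)
  }
  structure(
    list(id = id, sex = sex, age_years = age_years, weight_kg = weight_kg),
    class = "participant"
  )
}

#' @export
print.participant <- function(x, ...) {
  cat(sprintf("<participant> %s: %s, %d y, %.1f kg\n",
              x$id, x$sex, x$age_years, x$weight_kg))
  invisible(x)
}

#' Read participant metadata from a YAML or JSON sidecar file
#'
#' The sidecar must contain the fields `id`, `sex`, `age_years`, `weight_kg`.
#' Format is chosen by file extension (`.yaml`/`.yml` or `.json`).
#'
#' @param path Path to the sidecar file.
#' @return A [participant] object.
#' @export
read_participant <- function(path) {
  if (!file.exists(path)) {
    stop("participant file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  meta <- switch(ext,
    yaml = ,
    yml  = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path),
    stop("unsupported participant file extension: .", ext, call. = FALSE)
  )
  need <- c("id", "sex", "age_years", "weight_kg")
  missing <- setdiff(need, names(meta))
  if (length(missing)) {
    stop("participant file missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  participant(meta$id, meta$sex, meta$age_years, meta$weight_kg)
}

#' Construct a validated 7-day activity week
#'
#' An activity week is exactly 10,080 strictly consecutive minute records
#' (7 x 1,440) beginning at midnight. Each record carries the energy expended
#' in that minute (kcal), whether the device was worn, and whether the minute
#' has been imputed at basal rate.
#'
#' @param participant A [participant] object.
#' @param records A data frame with columns `timestamp` (POSIXct, minute
#'   resolution), `energy_kcal` (finite, >= 0), `worn` (logical) and
#'   optionally `imputed` (logical, default `FALSE`).
#' @param imputed Logical flag marking the week as having had its non-wear
#'   minutes imputed at basal rate.
#'
#' @return An object of class `activity_week`.
#' @export
activity_week <- function(participant, records, imputed = FALSE) {
  stopifnot(inherits(participant, "participant"), is.data.frame(records))
  need <- c("timestamp", "energy_kcal", "worn")
  missing <- setdiff(need, names(records))
  if (length(missing)) {
    stop("records missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"imputed" %in% names(records)) records$imputed <- FALSE
  records <- records[, c("timestamp", "energy_kcal", "worn", "imputed")]
  if (nrow(records) != MINUTES_PER_WEEK) {
    stop("an activity week must have exactly ", MINUTES_PER_WEEK,
         " minute records, got ", nrow(records), call. = FALSE)
  }
  ts <- records$timestamp
  if (!inherits(ts, "POSIXct")) {
    stop("timestamp column must be POSIXct", call. = FALSE)
  }
  lt <- as.POSIXlt(ts[1L])
  if (lt$hour != 0L || lt$min != 0L || lt$sec != 0) {
    stop("activity week does not commence at midnight (first record ",
         format(ts[1L], "%Y-%m-%dT%H:%M"), ")", call. = FALSE)
  }
  steps <- diff(as.numeric(ts))
  if (any(steps != 60)) {
    bad <- which(steps != 60)[1L]
    stop("records are not strictly consecutive minutes (gap or duplicate ",
         "after record ", bad, ", ", format(ts[bad], "%Y-%m-%dT%H:%M"), ")",
         call. = FALSE)
  }
  e <- records$energy_kcal
  if (!is.numeric(e) || any(!is.finite(e)) || any(e < 0)) {
    bad <- which(!is.finite(e) | e < 0)[1L]
    stop("energy_kcal must be finite and non-negative (record ", bad, ")",
         call. = FALSE)
  }
  if (!is.logical(records$worn) || anyNA(records$worn)) {
    stop("worn must be logical with no missing values", call. = FALSE)
  }
  structure(
    list(participant = participant, records = records),
    imputed = isTRUE(imputed),
    class = "activity_week"
  )
}

#' @export
print.activity_week <- function(x, ...) {
  r <- x$records
  cat(sprintf(
    "<activity_week> %s: %s to %s, %d min (%d non-wear%s)\n",
    x$participant$id,
    format(r$timestamp[1L], "%Y-%m-%d"),
    format(r$timestamp[nrow(r)], "%Y-%m-%d"),
    nrow(r), sum(!r$worn),
    if (isTRUE(attr(x, "imputed"))) ", imputed" else ""
  ))
  invisible(x)
}

week_is_imputed <- function(week) isTRUE(attr(week, "imputed"))

parse_minute_timestamps <- function(x) {
  # canonical dialect: ISO-8601 at minute resolution, naive local time,
  # "T" or space separator, optional ":00" seconds
  y <- sub("^(\\d{4}-\\d{2}-\\d{2})[T ](\\d{2}:\\d{2})(:00)?$", "\\1T\\2", x)
  ok <- grepl("^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}$", y)
  ts <- as.POSIXct(rep(NA_real_, length(x)), tz = "UTC")
  ts[ok] <- as.POSIXct(strptime(y[ok], "%Y-%m-%dT%H:%M", tz = "UTC"))
  ts
}

parse_worn_flag <- function(x) {
  z <- tolower(trimws(x))
  out <- rep(NA, length(z))
  out[z %in% c("true", "1")] <- TRUE
  out[z %in% c("false", "0")] <- FALSE
  out
}

#' Read a canonical minute-epoch activity CSV
#'
#' The canonical dialect has the header `timestamp,energy_kcal,worn`, one row
#' per minute, ISO-8601 minute timestamps in naive local time (no time-zone
#' offset; daylight-saving transitions are not representable and weeks
#' spanning them must be exported on a fixed clock), energy in kcal for that
#' minute, and `worn` as `true`/`false`. The file must start at midnight and
#' span at most 7 days. Minutes absent from the file are materialised as
#' non-wear records (energy 0, `worn = FALSE`) so that the full
#' 10,080-minute grid always holds; energy values of minutes present in the
#' file are never altered.
#'
#' @param path Path to the CSV file.
#' @param participant A [participant] object for the wearer.
#' @return A validated [activity_week].
#' @export
read_minute_csv <- function(path, participant) {
  if (!file.exists(path)) stop("activity file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  if (!identical(names(raw), c("timestamp", "energy_kcal", "worn"))) {
    stop("line 1: header must be 'timestamp,energy_kcal,worn', got '",
         paste(names(raw), collapse = ","), "'", call. = FALSE)
  }
  if (nrow(raw) == 0L) stop("file contains no data rows", call. = FALSE)
  lineno <- seq_len(nrow(raw)) + 1L  # header is line 1

  ts <- parse_minute_timestamps(raw$timestamp)
  if (anyNA(ts)) {
    bad <- lineno[which(is.na(ts))[1L]]
    stop("line ", bad, ": malformed timestamp '",
         raw$timestamp[is.na(ts)][1L],
         "' (expected ISO-8601 minute, e.g. 2015-03-02T08:00)", call. = FALSE)
  }
  energy <- suppressWarnings(as.numeric(raw$energy_kcal))
  if (any(!is.finite(energy) | energy < 0)) {
    bad <- which(!is.finite(energy) | energy < 0)[1L]
    stop("line ", lineno[bad], ": energy_kcal must be a finite non-negative ",
         "number, got '", raw$energy_kcal[bad], "'", call. = FALSE)
  }
  worn <- parse_worn_flag(raw$worn)
  if (anyNA(worn)) {
    bad <- which(is.na(worn))[1L]
    stop("line ", lineno[bad], ": worn must be 'true' or 'false', got '",
         raw$worn[bad], "'", call. = FALSE)
  }
  if (anyDuplicated(ts)) {
    bad <- which(duplicated(ts))[1L]
    stop("line ", lineno[bad], ": duplicate timestamp ",
         format(ts[bad], "%Y-%m-%dT%H:%M"), call. = FALSE)
  }
  ord <- order(ts)
  ts <- ts[ord]; energy <- energy[ord]; worn <- worn[ord]
  lineno <- lineno[ord]

  start <- ts[1L]
  lt <- as.POSIXlt(start)
  if (lt$hour != 0L || lt$min != 0L) {
    stop("line ", lineno[1L], ": recording does not commence at midnight ",
         "(first timestamp ", format(start, "%Y-%m-%dT%H:%M"), ")",
         call. = FALSE)
  }
  grid <- start + 60 * (seq_len(MINUTES_PER_WEEK) - 1L)
  beyond <- as.numeric(ts) >= as.numeric(grid[MINUTES_PER_WEEK]) + 60
  if (any(beyond)) {
    bad <- which(beyond)[1L]
    stop("line ", lineno[bad], ": timestamp ",
         format(ts[bad], "%Y-%m-%dT%H:%M"),
         " lies beyond the 7-day monitoring window", call. = FALSE)
  }

  # materialise the full grid; absent minutes become non-wear records
  idx <- as.integer(round((as.numeric(ts) - as.numeric(start)) / 60)) + 1L
  full_energy <- numeric(MINUTES_PER_WEEK)
  full_worn <- rep(FALSE, MINUTES_PER_WEEK)
  full_energy[idx] <- energy
  full_worn[idx] <- worn

  activity_week(
    participant,
    data.frame(timestamp = grid, energy_kcal = full_energy,
               worn = full_worn, imputed = FALSE)
  )
}

#' Write an activity week in the canonical minute CSV dialect
#'
#' Energy values are written with full double precision (`%.17g`) so that
#' reading the file back reproduces the in-memory week exactly.
#'
#' @param week An [activity_week].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_minute_csv <- function(week, path) {
  stopifnot(inherits(week, "activity_week"))
  r <- week$records
  lines <- c(
    "timestamp,energy_kcal,worn",
    sprintf("%s,%s,%s",
            format(r$timestamp, "%Y-%m-%dT%H:%M"),
            sprintf("%.17g", r$energy_kcal),
            ifelse(r$worn, "true", "false"))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a machine-readable profile report
#'
#' Serialises a five-dimension profile together with its traffic-light
#' attainment and the provenance needed to reproduce it (participant,
#' intensity thresholds, target set, software version) as JSON. The report
#' round-trips losslessly through [read_profile_report()].
#'
#' @param profile A [multidim_profile].
#' @param attainment A [score_profile()] result.
#' @param path Output JSON path.
#' @param thresholds The [intensity_thresholds] used (recorded as provenance).
#' @param targets The [target_set] used (recorded as provenance).
#' @return `path`, invisibly.
#' @export
write_profile_report <- function(profile, attainment, path,
                                 thresholds = intensity_thresholds(),
                                 targets = NULL) {
  stopifnot(inherits(profile, "multidim_profile"),
            inherits(attainment, "target_attainment"))
  pal_status <- classify_pal_status(profile$pal)
  report <- list(
    software = list(
      package = "activprofile",
      version = as.character(utils::packageVersion("activprofile"))
    ),
    thresholds = unclass(thresholds),
    targets = if (!is.null(targets)) {
      lapply(seq_len(nrow(targets)), function(i) {
        list(dimension = targets$dimension[i],
             target = targets$target[i],
             direction = targets$direction[i])
      })
    },
    profile = profile[PROFILE_DIMENSIONS],
    pal_status = pal_status,
    attainment = lapply(seq_len(nrow(attainment)), function(i) {
      list(dimension = attainment$dimension[i],
           value = attainment$value[i],
           target = attainment$target[i],
           direction = attainment$direction[i],
           status = attainment$status[i],
           relative_attainment = attainment$relative_attainment[i])
    })
  )
  # digits = I(17): lossless IEEE round-trip through JSON
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read a profile report written by [write_profile_report()]
#'
#' @param path Path to the report JSON.
#' @return A list with elements `profile` (a [multidim_profile]),
#'   `attainment` (a `target_attainment` data frame), `thresholds`,
#'   `pal_status` and `software`.
#' @export
read_profile_report <- function(path) {
  if (!file.exists(path)) stop("report not found: ", path, call. = FALSE)
  x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  profile <- structure(lapply(x$profile[PROFILE_DIMENSIONS], as.numeric),
                       class = "multidim_profile")
  att <- x$attainment
  att <- att[match(PROFILE_DIMENSIONS, att$dimension), , drop = FALSE]
  rownames(att) <- NULL
  class(att) <- c("target_attainment", "data.frame")
  list(profile = profile,
       attainment = att,
       thresholds = x$thresholds,
       pal_status = x$pal_status,
       software = x$software)
}
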