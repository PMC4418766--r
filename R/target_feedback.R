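#' Health-target set for the five activity dimensions
#'
#' A target set holds, for each of the five dimensions, a positive target
#' value in the dimension's own units and a direction: `at_least` (higher is
#' better; all movement dimensions) or `at_most` (lower is better; the
#' sedentary dimension). Appropriate target values depend on the guideline
#' framework in use, so they are configuration, not constants: see
#' [example_target_set()] for a worked example set shipped with the package.
#'
#' @param targets Named list (names = dimensions) of lists with fields
#'   `target` (positive number) and optionally `direction` (defaults:
#'   `at_most` for `sedentary_pct_waking`, `at_least` otherwise) and `label`.
#' @return An object of class `target_set`: a data frame with columns
#'   `dimension`, `target`, `direction`, `label`.
#' @export
#' @examples
#' target_set(list(
#'   pal = list(target = 1.7),
#'   sedentary_pct_waking = list(target = 65),
#'   daily_moderate_min = list(target = 30),
#'   weekly_bout_min = list(target = 150),
#'   weekly_vigorous_min = list(target = 75)
#' ))
target_set <- function(targets) {
  missing <- setdiff(PROFILE_DIMENSIONS, names(targets))
  if (length(missing)) {
    stop("target set missing dimension(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(PROFILE_DIMENSIONS, function(d) {
    t <- targets[[d]]
    value <- as.numeric(t$target)
    if (!is.finite(value) || value <= 0) {
      stop("target for ", d, " must be a positive number", call. = FALSE)
    }
    direction <- t$direction
    if (is.null(direction)) {
      direction <- if (d == "sedentary_pct_waking") "at_most" else "at_least"
    }
    direction <- match.arg(direction, c("at_least", "at_most"))
    label <- if (is.null(t$label)) unname(PROFILE_DIMENSION_LABELS[d]) else t$label
    data.frame(dimension = d, target = value, direction = direction,
               label = label)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("target_set", "data.frame")
  out
}

#' Read a target set from a YAML configuration file
#'
#' The file maps each dimension name to `target`, optional `direction` and
#' optional `label`; see `inst/extdata/targets_example.yaml` for the layout.
#'
#' @param path Path to the YAML file.
#' @return A [target_set].
#' @export
read_target_set <- function(path) {
  if (!file.exists(path)) stop("targets file not found: ", path, call. = FALSE)
  target_set(yaml::read_yaml(path))
}

#' Example target set shipped with the package
#'
#' Loads `extdata/targets_example.yaml`: a worked example built from widely
#' used public-health reference points (150 weekly minutes of sustained
#' moderate-vigorous activity, 75 weekly vigorous minutes, 30 daily moderate
#' minutes, PAL 1.70, at most 65% of the waking day sedentary). These are
#' illustrative configuration values, not endorsements; studies should
#' supply the target set of their chosen guideline framework.
#'
#' @return A [target_set].
#' @export
example_target_set <- function() {
  read_target_set(system.file("extdata", "targets_example.yaml",
                              package = "activprofile", mustWork = TRUE))
}

#' Score one dimension against its target with the traffic-light rule
#'
#' Status is green/amber/red ("hit"/"near"/"missed"): a target is hit when
#' met in its direction, near when within 25% of the target value, and
#' missed when more than 25% away. "Within 25%" is relative to the target
#' and inclusive at the boundary, so a value exactly 25% short (or, for
#' `at_most` targets, 25% over) is near.
#'
#' @param value Achieved dimension value, >= 0.
#' @param target Target value, > 0.
#' @param direction `"at_least"` or `"at_most"`.
#' @return A list with `status` (`"hit"`, `"near"` or `"missed"`) and
#'   `relative_attainment` (`value / target`).
#' @export
#' @examples
#' score_dimension(100, 150, "at_least")   # missed (more than 25% short)
#' score_dimension(120, 150, "at_least")   # near (within 25%)
score_dimension <- function(value, target, direction = c("at_least", "at_most")) {
  direction <- match.arg(direction)
  if (!is.finite(target) || target <= 0) {
    stop("target must be a positive number", call. = FALSE)
  }
  if (!is.finite(value) || value < 0) {
    stop("value must be finite and non-negative", call. = FALSE)
  }
  rel <- value / target
  status <- if (direction == "at_least") {
    if (value >= target) "hit"
    else if (value >= 0.75 * target) "near"
    else "missed"
  } else {
    if (value <= target) "hit"
    else if (value <= 1.25 * target) "near"
    else "missed"
  }
  list(status = status, relative_attainment = rel)
}

#' Score a full profile against a target set
#'
#' Applies [score_dimension()] to each of the five dimensions independently
#' (no cross-dimension coupling).
#'
#' @param profile A [multidim_profile].
#' @param targets A [target_set].
#' @return An object of class `target_attainment`: a data frame with one row
#'   per dimension and columns `dimension`, `label`, `value`, `target`,
#'   `direction`, `status`, `relative_attainment`.
#' @export
score_profile <- function(profile, targets) {
  stopifnot(inherits(profile, "multidim_profile"),
            inherits(targets, "target_set"))
  rows <- lapply(PROFILE_DIMENSIONS, function(d) {
    t <- targets[targets$dimension == d, ]
    s <- score_dimension(profile[[d]], t$target, t$direction)
    data.frame(dimension = d, label = t$label, value = profile[[d]],
               target = t$target, direction = t$direction,
               status = s$status, relative_attainment = s$relative_attainment)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("target_attainment", "data.frame")
  out
}

#' @export
print.target_attainment <- function(x, ...) {
  cat("<target_attainment>\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-34s %8.2f vs %8.2f (%s)  %s\n",
                x$label[i], x$value[i], x$target[i],
                sub("_", " ", x$direction[i]), toupper(x$status[i])))
  }
  invisible(x)
}

#' Classify overall activity status from PAL
#'
#' Maps PAL to the three conventional activity bands: sedentary
#' (PAL 1.40-1.69), moderately active (1.70-1.99) and highly active
#' (2.00-2.40). The printed bands leave hairline gaps and open ends; they
#' are resolved as contiguous half-open intervals, with values below 1.40
#' clamped to sedentary and above 2.40 to highly active.
#'
#' @param pal Physical activity level, > 0.
#' @return `"sedentary"`, `"moderately_active"` or `"highly_active"`.
#' @export
#' @examples
#' classify_pal_status(1.83)  # moderately_active
classify_pal_status <- function(pal) {
  if (!is.finite(pal) || pal <= 0) stop("pal must be positive", call. = FALSE)
  if (pal < 1.70) "sedentary"
  else if (pal < 2.00) "moderately_active"
  else "highly_active"
}
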