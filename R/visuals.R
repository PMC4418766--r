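# Deterministic hand-assembled SVG 1.1. Renderers are pure functions of
# (input, spec): no timestamps, random ids or environment state are embedded,
# so a fixed input always yields byte-identical output.

#' Rendering specification for the feedback infographics
#'
#' Colours and geometry for every renderer. The three status colours map the
#' traffic-light scores (green = hit, amber = near, red = missed); the five
#' band colours map the intensity bands. All eight colours must be pairwise
#' distinct so no graphic can conflate a status with a band.
#'
#' @param status_colours Named vector `c(hit=, near=, missed=)` of CSS
#'   colours.
#' @param band_colours Named vector over the five intensity bands.
#' @param width,height Canvas size in px.
#' @param font_family CSS font stack.
#' @param font_size Base font size in px.
#' @return An object of class `render_spec`.
#' @export
render_spec <- function(status_colours = c(hit = "#1a9850", near = "#fdae61",
                                           missed = "#d73027"),
                        band_colours = c(sedentary = "#c6c6c6",
                                         light = "#a6d96a",
                                         moderate = "#fee08b",
                                         vigorous = "#f46d43",
                                         very_vigorous = "#67001f"),
                        width = 760, height = 480,
                        font_family = "Helvetica, Arial, sans-serif",
                        font_size = 13) {
  if (!identical(sort(names(status_colours)), sort(c("hit", "near", "missed")))) {
    stop("status_colours must be named hit, near, missed", call. = FALSE)
  }
  if (!identical(sort(names(band_colours)), sort(INTENSITY_BANDS))) {
    stop("band_colours must cover the five intensity bands", call. = FALSE)
  }
  all_cols <- c(status_colours, band_colours)
  if (anyDuplicated(tolower(all_cols))) {
    stop("status and band colours must all be distinct", call. = FALSE)
  }
  structure(
    list(status_colours = status_colours, band_colours = band_colours,
         width = width, height = height, font_family = font_family,
         font_size = font_size),
    class = "render_spec"
  )
}

n2 <- function(x) sprintf("%.2f", x)

svg_open <- function(width, height, spec) {
  paste0(
    '<svg xmlns="http://www.w3.org/2000/svg" version="1.1" width="', width,
    '" height="', height, '" viewBox="0 0 ', width, ' ', height, '" ',
    'font-family="', spec$font_family, '" font-size="', spec$font_size, '">'
  )
}

svg_text <- function(x, y, label, anchor = "start", size = NULL,
                     weight = NULL, fill = "#333333") {
  paste0('<text x="', n2(x), '" y="', n2(y), '" text-anchor="', anchor, '"',
         if (!is.null(size)) paste0(' font-size="', size, '"'),
         if (!is.null(weight)) paste0(' font-weight="', weight, '"'),
         ' fill="', fill, '">', label, '</text>')
}

svg_rect <- function(x, y, w, h, fill, stroke = "none", extra = "") {
  paste0('<rect x="', n2(x), '" y="', n2(y), '" width="', n2(w),
         '" height="', n2(h), '" fill="', fill, '" stroke="', stroke, '"',
         extra, '/>')
}

svg_line <- function(x1, y1, x2, y2, stroke = "#333333", width = 1,
                     dash = NULL) {
  paste0('<line x1="', n2(x1), '" y1="', n2(y1), '" x2="', n2(x2),
         '" y2="', n2(y2), '" stroke="', stroke, '" stroke-width="', width,
         '"', if (!is.null(dash)) paste0(' stroke-dasharray="', dash, '"'),
         '/>')
}

svg_graphic <- function(lines) {
  structure(paste(lines, collapse = "\n"), class = "svg_graphic")
}

#' @export
print.svg_graphic <- function(x, ...) {
  cat("<svg_graphic> ", nchar(unclass(x)), " bytes\n", sep = "")
  invisible(x)
}

#' Write an SVG graphic to a file
#'
#' @param graphic An `svg_graphic` (any renderer's return value).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_svg <- function(graphic, path) {
  stopifnot(inherits(graphic, "svg_graphic"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(unclass(graphic), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

status_legend <- function(x, y, spec) {
  out <- character(0)
  labs <- c(hit = "hit", near = "near (within 25%)", missed = "missed (>25% away)")
  for (s in c("hit", "near", "missed")) {
    out <- c(out,
             svg_rect(x, y - 9, 12, 12, spec$status_colours[[s]]),
             svg_text(x + 18, y + 1, labs[[s]], size = spec$font_size - 2))
    x <- x + 60 + 7 * nchar(labs[[s]])
  }
  out
}

check_attainment <- function(attainment) {
  if (!inherits(attainment, "target_attainment") ||
      !all(PROFILE_DIMENSIONS %in% attainment$dimension)) {
    stop("attainment must score all five dimensions", call. = FALSE)
  }
  attainment[match(PROFILE_DIMENSIONS, attainment$dimension), , drop = FALSE]
}

#' Render the traffic-light wheel
#'
#' Five equal 72-degree segments, one per dimension, filled purely by status
#' colour: the wheel deliberately encodes no magnitude, so two attainments
#' with the same statuses render byte-identically whatever their values.
#'
#' @param attainment A [score_profile()] result covering all five
#'   dimensions.
#' @param spec A [render_spec].
#' @return An `svg_graphic`.
#' @export
render_wheel <- function(attainment, spec = render_spec()) {
  att <- check_attainment(attainment)
  w <- 460; h <- 480
  cx <- w / 2; cy <- 230; r <- 140
  body <- c(svg_open(w, h, spec),
            svg_text(cx, 36, "Health targets: activity wheel",
                     anchor = "middle", size = spec$font_size + 4,
                     weight = "bold"))
  for (i in seq_len(5L)) {
    a0 <- -pi / 2 + (i - 1L) * 2 * pi / 5
    a1 <- a0 + 2 * pi / 5
    x0 <- cx + r * cos(a0); y0 <- cy + r * sin(a0)
    x1 <- cx + r * cos(a1); y1 <- cy + r * sin(a1)
    fill <- spec$status_colours[[att$status[i]]]
    body <- c(body, paste0(
      '<path data-dim="', att$dimension[i], '" d="M ', n2(cx), ' ', n2(cy),
      ' L ', n2(x0), ' ', n2(y0), ' A ', n2(r), ' ', n2(r), ' 0 0 1 ',
      n2(x1), ' ', n2(y1), ' Z" fill="', fill,
      '" stroke="#ffffff" stroke-width="3"/>'
    ))
    am <- (a0 + a1) / 2
    lx <- cx + (r + 26) * cos(am); ly <- cy + (r + 26) * sin(am)
    anchor <- if (cos(am) > 0.3) "start" else if (cos(am) < -0.3) "end" else "middle"
    body <- c(body, svg_text(lx, ly + 4, att$label[i], anchor = anchor,
                             size = spec$font_size - 2))
  }
  body <- c(body, status_legend(40, h - 16, spec), "</svg>")
  svg_graphic(body)
}

#' Render the target-bar comparison
#'
#' For each dimension a grey reference bar represents the target (unit
#' length) and a status-coloured bar is scaled to the relative attainment.
#' Attainment beyond `cap` times the target is drawn at the cap with an
#' overflow marker so extreme values cannot blow out the layout.
#'
#' @inheritParams render_wheel
#' @param cap Maximum drawn relative attainment; default 2.
#' @return An `svg_graphic`.
#' @export
render_target_bars <- function(attainment, spec = render_spec(), cap = 2) {
  att <- check_attainment(attainment)
  w <- 640; row_h <- 62; x0 <- 230; bar_w <- 170; bar_h <- 16
  h <- 70 + 5 * row_h + 40
  body <- c(svg_open(w, h, spec),
            svg_text(w / 2, 36, "Health targets: target bars",
                     anchor = "middle", size = spec$font_size + 4,
                     weight = "bold"))
  for (i in seq_len(5L)) {
    y <- 70 + (i - 1L) * row_h
    rel <- att$relative_attainment[i]
    drawn <- min(rel, cap)
    fill <- spec$status_colours[[att$status[i]]]
    body <- c(body,
      svg_text(x0 - 12, y + bar_h + 10, att$label[i], anchor = "end",
               size = spec$font_size - 1),
      # reference bar: unit target length
      svg_rect(x0, y, bar_w, bar_h, "#e8e8e8", stroke = "#888888",
               extra = ' data-role="reference"'),
      svg_rect(x0, y + bar_h + 4, bar_w * drawn / 1, bar_h, fill,
               extra = paste0(' data-dim="', att$dimension[i],
                              '" data-role="attainment"')),
      svg_text(x0 + bar_w * drawn + 8, y + 2 * bar_h - 1,
               sprintf("%.0f%%", 100 * rel), size = spec$font_size - 2)
    )
    if (rel > cap) {
      body <- c(body, svg_text(x0 + bar_w * cap + 46, y + 2 * bar_h - 1,
                               "&#187;", size = spec$font_size + 2,
                               weight = "bold", fill = fill))
    }
    body <- c(body, svg_line(x0 + bar_w, y - 3, x0 + bar_w,
                             y + 2 * bar_h + 7, stroke = "#444444",
                             width = 1.5))
  }
  body <- c(body, status_legend(40, h - 14, spec), "</svg>")
  svg_graphic(body)
}

#' Render the bubble sliding scale
#'
#' Each dimension's performance is a status-coloured bubble on a horizontal
#' scale whose central line marks the target. Displacement is linear in
#' relative attainment, `relative_attainment - 1`, sign-flipped for
#' `at_most` dimensions so that "better than target" always plots to the
#' right, and clipped to `range` target-multiples either side.
#'
#' @inheritParams render_wheel
#' @param range Clipping half-range of the scale in target multiples;
#'   default 1 (i.e. the scale spans 0x to 2x the target).
#' @return An `svg_graphic`.
#' @export
render_bubble_scale <- function(attainment, spec = render_spec(), range = 1) {
  att <- check_attainment(attainment)
  w <- 640; row_h <- 58; x0 <- 240; track_w <- 320
  h <- 80 + 5 * row_h + 40
  xc <- x0 + track_w / 2
  body <- c(svg_open(w, h, spec),
            svg_text(w / 2, 36, "Health targets: bubble scale",
                     anchor = "middle", size = spec$font_size + 4,
                     weight = "bold"),
            svg_text(x0, 58, "short of target", size = spec$font_size - 3,
                     fill = "#777777"),
            svg_text(x0 + track_w, 58, "beyond target", anchor = "end",
                     size = spec$font_size - 3, fill = "#777777"))
  for (i in seq_len(5L)) {
    y <- 92 + (i - 1L) * row_h
    disp <- att$relative_attainment[i] - 1
    if (att$direction[i] == "at_most") disp <- -disp
    disp <- max(-range, min(range, disp))
    bx <- xc + disp / range * (track_w / 2 - 14)
    fill <- spec$status_colours[[att$status[i]]]
    body <- c(body,
      svg_text(x0 - 12, y + 4, att$label[i], anchor = "end",
               size = spec$font_size - 1),
      svg_line(x0, y, x0 + track_w, y, stroke = "#bbbbbb", width = 2),
      svg_line(xc, y - 16, xc, y + 16, stroke = "#444444", width = 2),
      paste0('<circle data-dim="', att$dimension[i], '" cx="', n2(bx),
             '" cy="', n2(y), '" r="11" fill="', fill,
             '" stroke="#ffffff" stroke-width="1.5"/>')
    )
  }
  body <- c(body,
            svg_text(xc, 92 + 5 * row_h - 24, "target",
                     anchor = "middle", size = spec$font_size - 3,
                     fill = "#444444"),
            status_legend(40, h - 14, spec), "</svg>")
  svg_graphic(body)
}

band_runs_for_day <- function(met_day, thresholds) {
  band <- as.integer(classify_minute(met_day, thresholds))
  r <- rle(band)
  ends <- cumsum(r$lengths)
  data.frame(start = ends - r$lengths + 1L, len = r$lengths, band = r$values)
}

day_strip_elems <- function(met_day, thresholds, spec, x0, y, width, height) {
  runs <- band_runs_for_day(met_day, thresholds)
  px <- width / MINUTES_PER_DAY
  vapply(seq_len(nrow(runs)), function(i) {
    svg_rect(x0 + (runs$start[i] - 1L) * px, y, runs$len[i] * px, height,
             spec$band_colours[[runs$band[i]]])
  }, character(1))
}

day_met_elems <- function(met_day, thresholds, spec, x0, y_base, width,
                          plot_h, met_max = 12) {
  px <- width / MINUTES_PER_DAY
  m <- pmin(met_day, met_max)
  pts <- paste(n2(x0 + (seq_along(m) - 0.5) * px),
               n2(y_base - m / met_max * plot_h), collapse = " ")
  cuts <- c(thresholds$sedentary_lt, thresholds$light_lt,
            thresholds$moderate_lt, thresholds$vigorous_lt)
  elems <- vapply(cuts, function(cv) {
    svg_line(x0, y_base - cv / met_max * plot_h, x0 + width,
             y_base - cv / met_max * plot_h, stroke = "#cccccc", width = 0.7,
             dash = "4 3")
  }, character(1))
  c(elems,
    paste0('<polyline points="', pts,
           '" fill="none" stroke="#2166ac" stroke-width="0.8"/>'))
}

hour_axis <- function(x0, y, width, spec, every = 3L) {
  hours <- seq(0L, 24L, by = every)
  px <- width / 24
  c(
    svg_line(x0, y, x0 + width, y, stroke = "#444444", width = 1),
    unlist(lapply(hours, function(hh) c(
      svg_line(x0 + hh * px, y, x0 + hh * px, y + 4, stroke = "#444444",
               width = 1),
      svg_text(x0 + hh * px, y + 16, sprintf("%02d:00", hh %% 24L),
               anchor = "middle", size = spec$font_size - 4)
    )))
  )
}

band_legend <- function(x, y, spec) {
  labs <- c(sedentary = "sedentary", light = "light", moderate = "moderate",
            vigorous = "vigorous", very_vigorous = "very vigorous")
  out <- character(0)
  for (b in INTENSITY_BANDS) {
    out <- c(out, svg_rect(x, y - 9, 12, 12, spec$band_colours[[b]]),
             svg_text(x + 17, y + 1, labs[[b]], size = spec$font_size - 3))
    x <- x + 40 + 6.2 * nchar(labs[[b]])
  }
  out
}

#' Render a minute-by-minute pattern for one day
#'
#' A 1,440-minute midnight-to-midnight trace of one calendar day, either as
#' a band-coloured strip (`mode = "strip"`) or as a MET-height line over
#' dashed cut-point guides (`mode = "met"`), with an hour axis and band
#' legend. These minute-level patterns are what let a wearer spot their
#' active and inactive times of day.
#'
#' @param week An [activity_week] (imputed or not; non-wear minutes display
#'   at 1 MET).
#' @param day_index Day of the week, 1--7.
#' @param bmr A [schofield_bmr()] result.
#' @param thresholds An [intensity_thresholds] object.
#' @param spec A [render_spec].
#' @param mode `"strip"` or `"met"`.
#' @return An `svg_graphic`.
#' @export
render_day_pattern <- function(week, day_index, bmr,
                               thresholds = intensity_thresholds(),
                               spec = render_spec(), mode = c("strip", "met")) {
  mode <- match.arg(mode)
  stopifnot(day_index %in% 1:7)
  met <- met_series(week, bmr)
  idx <- ((day_index - 1L) * MINUTES_PER_DAY + 1L):(day_index * MINUTES_PER_DAY)
  met_day <- met[idx]
  date_lab <- format(week$records$timestamp[idx[1L]], "%A %Y-%m-%d")
  w <- 760; x0 <- 30; plot_w <- 700
  h <- if (mode == "strip") 180 else 240
  body <- c(svg_open(w, h, spec),
            svg_text(w / 2, 28, paste0("Activity pattern: ", date_lab),
                     anchor = "middle", size = spec$font_size + 3,
                     weight = "bold"))
  if (mode == "strip") {
    body <- c(body,
              day_strip_elems(met_day, thresholds, spec, x0, 50, plot_w, 60),
              hour_axis(x0, 112, plot_w, spec))
  } else {
    body <- c(body,
              day_met_elems(met_day, thresholds, spec, x0, 170, plot_w, 130),
              svg_text(x0 - 6, 46, "MET", anchor = "end",
                       size = spec$font_size - 3),
              hour_axis(x0, 172, plot_w, spec))
  }
  body <- c(body, band_legend(x0, h - 14, spec), "</svg>")
  svg_graphic(body)
}

#' Render the whole week as seven stacked day strips
#'
#' Seven midnight-to-midnight band-coloured strips sharing one hour axis,
#' one row per calendar day.
#'
#' @inheritParams render_day_pattern
#' @return An `svg_graphic`.
#' @export
render_week_pattern <- function(week, bmr,
                                thresholds = intensity_thresholds(),
                                spec = render_spec()) {
  met <- met_series(week, bmr)
  w <- 760; x0 <- 90; plot_w <- 640; strip_h <- 30; gap <- 8
  h <- 60 + 7 * (strip_h + gap) + 70
  body <- c(svg_open(w, h, spec),
            svg_text(w / 2, 28, "Activity pattern: monitored week",
                     anchor = "middle", size = spec$font_size + 3,
                     weight = "bold"))
  for (d in 1:7) {
    idx <- ((d - 1L) * MINUTES_PER_DAY + 1L):(d * MINUTES_PER_DAY)
    y <- 52 + (d - 1L) * (strip_h + gap)
    body <- c(body,
              svg_text(x0 - 8, y + strip_h / 2 + 4,
                       format(week$records$timestamp[idx[1L]], "%a"),
                       anchor = "end", size = spec$font_size - 2),
              day_strip_elems(met[idx], thresholds, spec, x0, y, plot_w,
                              strip_h))
  }
  axis_y <- 52 + 7 * (strip_h + gap) + 2
  body <- c(body, hour_axis(x0, axis_y, plot_w, spec),
            band_legend(x0, h - 14, spec), "</svg>")
  svg_graphic(body)
}

#' Render the time/energy-by-intensity summary
#'
#' Paired bar charts of minutes and kcal per intensity band over the week;
#' the value printed above each bar equals the input tally (minutes as
#' integers, kcal to one decimal). `mode` selects the time chart, the energy
#' chart, or both side by side.
#'
#' @param band_totals A [time_and_energy_by_band()] result.
#' @param spec A [render_spec].
#' @param mode `"both"`, `"time"` or `"energy"`.
#' @return An `svg_graphic`.
#' @export
render_intensity_summary <- function(band_totals, spec = render_spec(),
                                     mode = c("both", "time", "energy")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(band_totals),
            all(c("band", "minutes", "kcal") %in% names(band_totals)))
  bt <- band_totals[match(INTENSITY_BANDS, band_totals$band), , drop = FALSE]
  panels <- switch(mode, both = c("time", "energy"), time = "time",
                   energy = "energy")
  panel_w <- 330; w <- 50 + length(panels) * (panel_w + 30); h <- 420
  body <- c(svg_open(w, h, spec),
            svg_text(w / 2, 28, "Time and energy by intensity",
                     anchor = "middle", size = spec$font_size + 3,
                     weight = "bold"))
  px0 <- 40
  for (p in panels) {
    vals <- if (p == "time") bt$minutes else bt$kcal
    labs <- if (p == "time") sprintf("%d", as.integer(round(vals)))
            else sprintf("%.1f", vals)
    title <- if (p == "time") "Time (min/week)" else "Energy (kcal/week)"
    vmax <- max(vals, 1)
    bw <- 46; gap <- (panel_w - 5 * bw) / 6
    base_y <- 330; plot_h <- 240
    body <- c(body, svg_text(px0 + panel_w / 2, 64, title, anchor = "middle",
                             size = spec$font_size, weight = "bold"),
              svg_line(px0, base_y, px0 + panel_w, base_y,
                       stroke = "#444444", width = 1))
    for (i in seq_len(5L)) {
      bh <- vals[i] / vmax * plot_h
      bx <- px0 + gap + (i - 1L) * (bw + gap)
      body <- c(body,
                svg_rect(bx, base_y - bh, bw, bh,
                         spec$band_colours[[bt$band[i]]],
                         extra = paste0(' data-band="', bt$band[i], '"')),
                svg_text(bx + bw / 2, base_y - bh - 6, labs[i],
                         anchor = "middle", size = spec$font_size - 3))
    }
    px0 <- px0 + panel_w + 30
  }
  body <- c(body, band_legend(40, h - 14, spec), "</svg>")
  svg_graphic(body)
}
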