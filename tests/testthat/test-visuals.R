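# extract fill colours in dimension order from data-dim attributed elements
dim_fills <- function(svg, tag = "path") {
  txt <- unclass(svg)
  m <- gregexpr(paste0("<", tag, "[^>]*data-dim=\"([a-z_]+)\"[^>]*>"), txt)
  elems <- regmatches(txt, m)[[1]]
  dims <- sub('.*data-dim="([a-z_]+)".*', "\\1", elems)
  fills <- sub('.*fill="([^"]+)".*', "\\1", elems)
  setNames(fills, dims)
}

status_colour_map <- function(spec = render_spec()) spec$status_colours

test_that("render spec enforces distinct status and band colours", {
  expect_s3_class(render_spec(), "render_spec")
  expect_error(render_spec(status_colours = c(hit = "#111111",
                                              near = "#111111",
                                              missed = "#222222")),
               "distinct")
  expect_error(render_spec(band_colours = c(sedentary = "#c6c6c6",
                                            light = "#a6d96a",
                                            moderate = "#fee08b",
                                            vigorous = "#f46d43")),
               "five intensity bands")
})

test_that("renderers are pure: repeated rendering is byte-identical", {
  set.seed(131)
  att <- random_attainment()
  wk <- met_week(random_met_series(), imputed = TRUE)
  bmr <- fix_bmr()
  bt <- time_and_energy_by_band(wk, bmr)
  expect_identical(unclass(render_wheel(att)), unclass(render_wheel(att)))
  expect_identical(unclass(render_target_bars(att)),
                   unclass(render_target_bars(att)))
  expect_identical(unclass(render_bubble_scale(att)),
                   unclass(render_bubble_scale(att)))
  expect_identical(unclass(render_day_pattern(wk, 3, bmr)),
                   unclass(render_day_pattern(wk, 3, bmr)))
  expect_identical(unclass(render_intensity_summary(bt)),
                   unclass(render_intensity_summary(bt)))
  # and byte-identical on disk
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_svg(render_wheel(att), f1); write_svg(render_wheel(att), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("wheel has five equal segments coloured purely by status", {
  targets <- example_target_set()
  hit_all <- structure(list(pal = 2, sedentary_pct_waking = 50,
                            daily_moderate_min = 60, weekly_bout_min = 200,
                            weekly_vigorous_min = 80),
                       class = "multidim_profile")
  att <- score_profile(hit_all, targets)
  fills <- dim_fills(render_wheel(att))
  expect_length(fills, 5L)
  expect_true(all(fills == status_colour_map()[["hit"]]))

  # archetype-A pattern: one green, four red
  a_like <- structure(list(pal = 1.2, sedentary_pct_waking = 90,
                           daily_moderate_min = 10, weekly_bout_min = 90,
                           weekly_vigorous_min = 80),
                      class = "multidim_profile")
  att_a <- score_profile(a_like, targets)
  fills <- dim_fills(render_wheel(att_a))
  expect_identical(sum(fills == status_colour_map()[["hit"]]), 1L)
  expect_identical(sum(fills == status_colour_map()[["missed"]]), 4L)
  expect_identical(names(fills)[fills == status_colour_map()[["hit"]]],
                   "weekly_vigorous_min")

  # no magnitude encoding: same statuses, different values, identical bytes
  a_scaled <- a_like
  a_scaled$weekly_vigorous_min <- 200   # still hit
  a_scaled$pal <- 0.9                   # still missed
  att_s <- score_profile(a_scaled, targets)
  expect_identical(unclass(render_wheel(att_a)), unclass(render_wheel(att_s)))

  # a missing dimension is an error
  expect_error(render_wheel(att_a[1:4, ]), "five dimensions")
})

test_that("target bars scale with relative attainment and cap with overflow", {
  targets <- example_target_set()
  prof <- structure(list(pal = 1.70, sedentary_pct_waking = 65 / 2,
                         daily_moderate_min = 15, weekly_bout_min = 450,
                         weekly_vigorous_min = 75),
                    class = "multidim_profile")
  att <- score_profile(prof, targets)
  svg <- unclass(render_target_bars(att, cap = 2))
  m <- gregexpr('<rect[^>]*data-dim="([a-z_]+)"[^>]*data-role="attainment"[^>]*/>',
                svg)
  rects <- regmatches(svg, m)[[1]]
  dims <- sub('.*data-dim="([a-z_]+)".*', "\\1", rects)
  widths <- as.numeric(sub('.*width="([0-9.]+)".*', "\\1", rects))
  names(widths) <- dims
  bar_w <- 170
  expect_equal(widths[["pal"]], bar_w)                       # rel 1.0 == ref
  expect_equal(widths[["daily_moderate_min"]], bar_w * 0.5)  # rel 0.5 half
  expect_equal(widths[["weekly_bout_min"]], bar_w * 2)       # capped at 2x
  expect_true(grepl("&#187;", svg))                          # overflow marker
  # half-length bar on an at_least dimension far short is red
  fills <- sub('.*fill="([^"]+)".*', "\\1", rects)
  names(fills) <- dims
  expect_identical(fills[["daily_moderate_min"]],
                   status_colour_map()[["missed"]])
})

test_that("bubble scale positions bubbles by direction-aware displacement", {
  targets <- example_target_set()
  prof <- structure(list(pal = 1.70, sedentary_pct_waking = 65 * 1.25,
                         daily_moderate_min = 45, weekly_bout_min = 75,
                         weekly_vigorous_min = 37.5),
                    class = "multidim_profile")
  att <- score_profile(prof, targets)
  svg <- unclass(render_bubble_scale(att))
  m <- gregexpr('<circle[^>]*data-dim="([a-z_]+)"[^>]*/>', svg)
  circles <- regmatches(svg, m)[[1]]
  dims <- sub('.*data-dim="([a-z_]+)".*', "\\1", circles)
  cx <- as.numeric(sub('.*cx="([0-9.]+)".*', "\\1", circles))
  fills <- sub('.*fill="([^"]+)".*', "\\1", circles)
  names(cx) <- dims; names(fills) <- dims
  centre <- 240 + 320 / 2
  # value exactly at target sits on the central line
  expect_equal(cx[["pal"]], centre)
  # at_most sedentary 1.25x target plots on the worse (left) side, amber
  expect_lt(cx[["sedentary_pct_waking"]], centre)
  expect_identical(fills[["sedentary_pct_waking"]],
                   status_colour_map()[["near"]])
  # at_least beyond-centre direction: 1.5x moderate plots right of centre
  expect_gt(cx[["daily_moderate_min"]], centre)
  # displacement is linear and clipped symmetrically
  expect_equal(centre - cx[["weekly_vigorous_min"]],
               (centre - cx[["weekly_bout_min"]]) * 1.0)
})

test_that("day pattern strip places band-coloured blocks at the right minutes", {
  bmr <- fix_bmr()
  # all-basal day: a single sedentary-colour strip
  svg <- unclass(render_day_pattern(flat_week(1, imputed = TRUE), 1, bmr))
  spec <- render_spec()
  strip_rects <- function(s) {
    regmatches(s, gregexpr('<rect [^>]*y="50\\.00" width="[^"]*" height="60\\.00" fill="[^"]*"[^>]*/>', s))[[1]]
  }
  rects <- strip_rects(svg)
  expect_length(rects, 1L)  # one merged run covering the whole day
  expect_true(grepl(spec$band_colours[["sedentary"]], rects, fixed = TRUE))
  # 30-min 5-MET block at 07:00 on day 2 appears as one moderate rect
  met <- rep(1, 10080)
  met[1440 + 420 + (1:30)] <- 5
  wk <- met_week(met, imputed = TRUE)
  svg <- unclass(render_day_pattern(wk, 2, bmr))
  px <- 700 / 1440
  expected_x <- sprintf("%.2f", 30 + 420 * px)
  expected_w <- sprintf("%.2f", 30 * px)
  pat <- paste0('<rect x="', expected_x, '" y="50.00" width="', expected_w,
                '"[^>]*fill="', spec$band_colours[["moderate"]], '"')
  expect_true(grepl(pat, svg))
  # the week render stacks seven day strips over one shared axis
  svg_w <- unclass(render_week_pattern(wk, bmr))
  expect_identical(lengths(regmatches(svg_w, gregexpr("<text[^>]*>Mon</text>",
                                                      svg_w))), 1L)
  for (d in c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")) {
    expect_true(grepl(paste0(">", d, "</text>"), svg_w))
  }
  expect_identical(lengths(regmatches(svg_w, gregexpr(">00:00<", svg_w))), 2L)
})

test_that("intensity summary prints the exact band totals and conserves time", {
  bmr <- fix_bmr()
  met <- rep(1, 10080); met[1:250] <- 4; met[301:400] <- 7
  wk <- met_week(met, imputed = TRUE)
  bt <- time_and_energy_by_band(wk, bmr)
  expect_identical(sum(bt$minutes), 10080L)
  svg <- unclass(render_intensity_summary(bt))
  expect_true(grepl(">9730<", svg))  # sedentary minutes label
  expect_true(grepl(">250<", svg))   # moderate minutes label
  expect_true(grepl(">100<", svg))   # vigorous minutes label
  for (k in sprintf("%.1f", bt$kcal)) {
    expect_true(grepl(paste0(">", k, "<"), svg, fixed = TRUE))
  }
  # all-basal week: only the sedentary bar is non-zero
  bt0 <- time_and_energy_by_band(flat_week(1, imputed = TRUE), bmr)
  svg0 <- unclass(render_intensity_summary(bt0, mode = "time"))
  m <- gregexpr('<rect[^>]*data-band="([a-z_]+)"[^>]*/>', svg0)
  rects <- regmatches(svg0, m)[[1]]
  h <- as.numeric(sub('.*height="([0-9.]+)".*', "\\1", rects))
  expect_identical(sum(h > 0), 1L)
})

test_that("every target graphic colours dimensions exactly by their status", {
  set.seed(141)
  spec <- render_spec()
  for (i in 1:25) {
    att <- random_attainment()
    expected <- unname(spec$status_colours[att$status])
    expect_identical(unname(dim_fills(render_wheel(att), "path")), expected)
    expect_identical(unname(dim_fills(render_bubble_scale(att), "circle")),
                     expected)
    svg <- unclass(render_target_bars(att))
    m <- gregexpr('<rect[^>]*data-dim="[a-z_]+"[^>]*/>', svg)
    fills <- sub('.*fill="([^"]+)".*', "\\1", regmatches(svg, m)[[1]])
    expect_identical(fills, expected)
  }
})
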