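# Chart template: the exact geometry of the standard German 24-hour IOP form
# in canonical pixel coordinates. All downstream position-based operations
# (gridline snapping, pressure calibration, header regions) read from this
# object, so generator and extractor share one source of geometric truth.

#' The five daily measurement times, in chart order
#'
#' Goldmann readings at 10 am, 2 pm, 5 pm and 9 pm, plus the midnight Perkins
#' reading. Midnight is charted after 9 pm and belongs to the following
#' calendar day.
#' @export
SLOT_TIMES <- c("10:00", "14:00", "17:00", "21:00", "00:00")

# Clock hours used for circular (24 h) arithmetic; midnight = 24.
SLOT_HOURS <- c(10, 14, 17, 21, 24)

#' Construct a chart template
#'
#' Defines the canonical geometry: canonical raster size, the x positions of
#' the time slots across up to six days (the form's time axis is nonlinear --
#' intervals between measurement times are uneven), the piecewise-linear
#' pressure axis (linear from 0 to 40 mmHg, compressed to half pixel density
#' from 40 to `y_max_mmhg`), and the header rectangles holding the printed
#' name label and the handwritten date.
#'
#' @param canonical_width,canonical_height canonical raster size in px.
#' @param days number of day columns on the form (1 to 6).
#' @param y_max_mmhg top of the pressure axis (default 80 mmHg).
#' @return object of class `chart_template`.
#' @export
chart_template <- function(canonical_width = 1200, canonical_height = 800,
                           days = 6, y_max_mmhg = 80) {
  W <- as.integer(canonical_width); H <- as.integer(canonical_height)
  if (W < 300 || H < 200) iop_error("InputError", "canonical size too small")
  days <- as.integer(days)
  if (days < 1 || days > 6) iop_error("InputError", "days must be in 1..6")

  # Pressure axis anchors: 0 mmHg near the bottom, 40 at the linear/compressed
  # break, y_max at the top of the axis band.
  y0  <- round(0.925 * H)   # 0 mmHg baseline
  y40 <- round(0.425 * H)   # 40 mmHg break (10 px/mmHg at H = 800)
  ymx <- round(0.175 * H)   # top anchor, half density above 40

  x_left  <- round(0.085 * W)
  x_right <- round(0.985 * W)
  day_w   <- (x_right - x_left) / 6   # form always rules 6 day columns
  # Uneven within-day offsets mirroring the uneven measurement intervals.
  offs <- c(0.10, 0.32, 0.50, 0.72, 0.88)
  slots <- do.call(rbind, lapply(seq_len(days) - 1L, function(d) {
    data.frame(day = d, clock = SLOT_TIMES,
               x = round(x_left + day_w * (d + offs)))
  }))
  rownames(slots) <- NULL

  structure(list(
    canonical_size = c(width = W, height = H),
    days = days,
    y_axis = list(mmhg = c(0, 40, y_max_mmhg), y_px = c(y0, y40, ymx)),
    time_slots = slots,
    header_region = round(c(0.05 * W, 0.0125 * H, 0.45 * W, 0.105 * H)),
    date_region   = round(c(0.55 * W, 0.0125 * H, 0.95 * W, 0.105 * H))
  ), class = "chart_template")
}

#' Map canonical y pixel to IOP in mmHg
#'
#' Inverse of the form's pressure axis: piecewise linear, strictly decreasing
#' in `y_px`, with the density change at 40 mmHg.
#'
#' @param y_px numeric vector of canonical y pixels.
#' @param template a [chart_template()].
#' @return IOP values in mmHg, at full (sub-unit) resolution.
#' @export
pixel_to_value <- function(y_px, template) {
  ax <- template$y_axis
  bad <- y_px > ax$y_px[1] + 0.5 | y_px < ax$y_px[3] - 0.5
  if (any(bad))
    iop_error("RangeError", sprintf(
      "pixel_to_value: y = %s outside the calibrated axis band [%d, %d]",
      paste(round(y_px[bad], 1), collapse = ", "), ax$y_px[3], ax$y_px[1]))
  stats::approx(x = ax$y_px, y = ax$mmhg, xout = y_px, rule = 1)$y
}

#' Map IOP in mmHg to canonical y pixel
#'
#' @param mmhg numeric vector of IOP values within the axis range.
#' @param template a [chart_template()].
#' @return fractional canonical y pixels.
#' @export
value_to_pixel <- function(mmhg, template) {
  ax <- template$y_axis
  bad <- mmhg < ax$mmhg[1] | mmhg > ax$mmhg[3]
  if (any(bad))
    iop_error("RangeError", sprintf(
      "value_to_pixel: value(s) %s outside the axis range [%g, %g] mmHg",
      paste(round(mmhg[bad], 2), collapse = ", "), ax$mmhg[1], ax$mmhg[3]))
  stats::approx(x = ax$mmhg, y = ax$y_px, xout = mmhg, rule = 1)$y
}

# Slot x positions for a given day span, and local inter-slot spacing.
template_slot_x <- function(template, days = template$days) {
  template$time_slots[template$time_slots$day < days, , drop = FALSE]
}

#' Write / read a template as a YAML config
#'
#' Stores the constructor parameters plus the derived anchor positions, so a
#' custom form layout can be versioned alongside extraction outputs.
#'
#' @param template a [chart_template()].
#' @param path file path.
#' @return `read_template` returns a [chart_template()].
#' @export
write_template <- function(template, path) {
  yaml::write_yaml(list(
    canonical_width = unname(template$canonical_size["width"]),
    canonical_height = unname(template$canonical_size["height"]),
    days = template$days,
    y_max_mmhg = template$y_axis$mmhg[3]
  ), path)
  invisible(path)
}

#' @rdname write_template
#' @export
read_template <- function(path) {
  cfg <- yaml::read_yaml(path)
  chart_template(cfg$canonical_width, cfg$canonical_height,
                 days = cfg$days, y_max_mmhg = cfg$y_max_mmhg)
}

#' @export
print.chart_template <- function(x, ...) {
  cat("<chart_template> canonical ", x$canonical_size["width"], " x ",
      x$canonical_size["height"], " px, ", x$days, " day(s), axis 0-",
      x$y_axis$mmhg[3], " mmHg (compressed above 40)\n", sep = "")
  invisible(x)
}
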