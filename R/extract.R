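# Value extraction: detect the vertical time gridlines (edge detection +
# restricted Hough transform), build the pixel<->value calibration from the
# template, segment the blue/red marks with HSV masks, and convert blob
# positions to timestamped IOP values.

#' Canny-style edge detection
#'
#' Sobel gradients, non-maximum suppression along the quantized gradient
#' direction, and double-threshold hysteresis (weak edges survive only in
#' components containing a strong edge).
#'
#' @param gray grayscale matrix in `[0, 1]`.
#' @param low,high hysteresis thresholds on gradient magnitude.
#' @return logical edge matrix.
#' @export
canny_edges <- function(gray, low = 0.08, high = 0.2) {
  h <- nrow(gray); w <- ncol(gray)
  pad <- gray[c(1, seq_len(h), h), c(1, seq_len(w), w)]
  ix <- function(dy, dx) pad[(seq_len(h)) + 1 + dy, (seq_len(w)) + 1 + dx]
  gx <- (ix(-1, 1) + 2 * ix(0, 1) + ix(1, 1)) -
        (ix(-1, -1) + 2 * ix(0, -1) + ix(1, -1))
  gy <- (ix(1, -1) + 2 * ix(1, 0) + ix(1, 1)) -
        (ix(-1, -1) + 2 * ix(-1, 0) + ix(-1, 1))
  mag <- sqrt(gx^2 + gy^2)
  # quantize direction into 4 sectors and suppress non-maxima
  ang <- atan2(gy, gx)
  sector <- (round(ang / (pi / 4)) %% 4)
  magp <- matrix(0, h + 2, w + 2); magp[2:(h + 1), 2:(w + 1)] <- mag
  mx <- function(dy, dx) magp[(seq_len(h)) + 1 + dy, (seq_len(w)) + 1 + dx]
  n1 <- mx(0, 1) * (sector == 0) + mx(1, 1) * (sector == 1) +
    mx(1, 0) * (sector == 2) + mx(1, -1) * (sector == 3)
  n2 <- mx(0, -1) * (sector == 0) + mx(-1, -1) * (sector == 1) +
    mx(-1, 0) * (sector == 2) + mx(-1, 1) * (sector == 3)
  keep <- mag >= n1 & mag >= n2
  strong <- keep & mag >= high
  weak <- keep & mag >= low
  if (!any(strong)) return(strong)
  lab <- label_components(weak)
  ids <- unique(lab[strong])
  weak & matrix(lab %in% ids[ids > 0], h, w)
}

#' Detect the vertical time gridlines
#'
#' Runs edge detection on the canonical chart and a Hough transform
#' restricted to near-vertical lines (at most `angle_max_deg` from vertical,
#' which also discards horizontal rulings), merges collinear votes closer
#' than `min_line_gap` px, and snaps each surviving line to the nearest
#' template slot position within `snap_tol` px. Returns one line per
#' detected slot.
#'
#' @param chart a `canonical_chart`.
#' @param days how many day columns to calibrate (default: template's count).
#' @param angle_max_deg maximum deviation from vertical, degrees.
#' @param snap_tol maximum distance (px) between a detected line and the
#'   template slot it is assigned to.
#' @param min_line_gap lines closer than this merge into one.
#' @param min_support_frac minimum edge support as a fraction of the plot
#'   band height.
#' @return data frame with one row per detected slot: `x_px`, `day`, `clock`,
#'   `support`.
#' @export
detect_time_lines <- function(chart, days = NULL, angle_max_deg = 5,
                              snap_tol = 10, min_line_gap = 8,
                              min_support_frac = 0.4) {
  template <- chart$template
  if (is.null(days)) days <- template$days
  gray <- to_gray(chart)
  ax <- template$y_axis
  band <- (ax$y_px[3] - 10):(ax$y_px[1] + 10)
  band <- band[band >= 1 & band <= nrow(gray)]
  edges <- canny_edges(gray[band, , drop = FALSE])
  ij <- which(edges, arr.ind = TRUE)
  slots <- template_slot_x(template, days)
  if (nrow(ij) == 0L)
    iop_error("CalibrationError", "detect_time_lines: no edges in the plot band")

  ys <- ij[, 1]; xs <- ij[, 2]
  yc <- (length(band) + 1) / 2
  w <- ncol(gray)
  thetas <- seq(-angle_max_deg, angle_max_deg, by = 0.5) * pi / 180
  best_votes <- integer(w); best_theta <- numeric(w)
  for (th in thetas) {
    x0 <- round(xs - (ys - yc) * tan(th))
    x0 <- x0[x0 >= 1 & x0 <= w]
    v <- tabulate(x0, nbins = w)
    upd <- v > best_votes
    best_theta[upd] <- th
    best_votes[upd] <- v[upd]
  }
  min_support <- min_support_frac * diff(range(band))
  peaks <- which(best_votes >= min_support)
  if (length(peaks) == 0L)
    iop_error("CalibrationError", "detect_time_lines: no vertical lines found")
  # merge neighboring peak columns into one line each
  grp <- cumsum(c(1L, diff(peaks) > min_line_gap))
  lines <- do.call(rbind, lapply(split(peaks, grp), function(px) {
    v <- best_votes[px]
    data.frame(x_px = sum(px * v) / sum(v), support = max(v))
  }))

  # snap to template slots; keep the best-supported line per slot
  lines$slot <- NA_integer_
  d <- abs(outer(lines$x_px, slots$x, "-"))
  lines$slot <- apply(d, 1, which.min)
  lines$dist <- d[cbind(seq_len(nrow(lines)), lines$slot)]
  lines <- lines[lines$dist <= snap_tol, , drop = FALSE]
  if (nrow(lines) > 0L) {
    lines <- lines[order(lines$slot, -lines$support), , drop = FALSE]
    lines <- lines[!duplicated(lines$slot), , drop = FALSE]
  }
  if (nrow(lines) < 3L)
    iop_error("CalibrationError", sprintf(
      "detect_time_lines: only %d of %d slots detected", nrow(lines), nrow(slots)))
  out <- data.frame(x_px = lines$x_px,
                    day = slots$day[lines$slot],
                    clock = slots$clock[lines$slot],
                    support = lines$support)
  out[order(out$day, match(out$clock, SLOT_TIMES)), , drop = FALSE]
}

#' Color-specific mask for one eye
#'
#' HSV thresholding: blue hues (200-260 degrees) mark the right eye (OD),
#' red hues (<= 20 or >= 340 degrees) the left eye (OS); both require
#' saturation >= 0.30 and value >= 0.20. The two masks are disjoint by
#' construction.
#'
#' @param chart a `canonical_chart` (or RGB array).
#' @param eye `"OD"` (blue) or `"OS"` (red).
#' @param sat_min,val_min saturation / value floors.
#' @return logical matrix.
#' @export
color_mask <- function(chart, eye = c("OD", "OS"), sat_min = 0.30, val_min = 0.20) {
  eye <- match.arg(eye)
  px <- ensure_rgb(chart_pixels(chart))
  d <- dim(px)
  rgbm <- rbind(as.vector(px[, , 1]), as.vector(px[, , 2]), as.vector(px[, , 3]))
  hsv <- grDevices::rgb2hsv(rgbm, maxColorValue = 1)
  hdeg <- hsv[1, ] * 360
  hue_ok <- if (eye == "OD") hdeg >= 200 & hdeg <= 260 else hdeg <= 20 | hdeg >= 340
  m <- hue_ok & hsv[2, ] >= sat_min & hsv[3, ] >= val_min
  matrix(m, d[1], d[2])
}

#' Extract IOP entries for one eye
#'
#' Searches the eye's color mask in the immediate vicinity of each detected
#' time line (a window of `vicinity_frac` of the local inter-slot spacing on
#' each side), labels connected components, rejects components whose
#' vertical extent exceeds `stroke_max_mmhg` (connecting polyline strokes),
#' and keeps the largest remaining component per line as the entry -- its
#' y-centroid mapped through the template's pressure axis gives the value at
#' 0.1 mmHg resolution. Additional accepted components are returned flagged
#' `"extra"`; they surface as false positives in evaluation.
#'
#' @param chart a `canonical_chart`.
#' @param lines output of [detect_time_lines()].
#' @param eye `"OD"` or `"OS"`.
#' @param vicinity_frac half-window as a fraction of local slot spacing.
#' @param stroke_max_mmhg reject blobs taller than this many mmHg.
#' @param min_blob_px minimum blob area in px.
#' @return data frame: `eye`, `day`, `clock`, `value_mmhg`, `x_px`, `y_px`,
#'   `blob_area`, `flag` (`""` or `"extra"`).
#' @export
extract_entries <- function(chart, lines, eye = c("OD", "OS"),
                            vicinity_frac = 0.4, stroke_max_mmhg = 6,
                            min_blob_px = 9L) {
  eye <- match.arg(eye)
  template <- chart$template
  mask <- color_mask(chart, eye)
  ax <- template$y_axis
  ylo <- max(1L, ax$y_px[3] - 5L); yhi <- min(nrow(mask), ax$y_px[1] + 5L)
  slots_all <- sort(template$time_slots$x)
  res <- list()
  for (i in seq_len(nrow(lines))) {
    x0 <- lines$x_px[i]
    gaps <- abs(slots_all - x0); gaps <- gaps[gaps > 1]
    vic <- vicinity_frac * min(gaps)
    xlo <- max(1L, floor(x0 - vic)); xhi <- min(ncol(mask), ceiling(x0 + vic))
    sub <- mask[ylo:yhi, xlo:xhi, drop = FALSE]
    if (!any(sub)) next
    lab <- label_components(sub)
    comps <- list()
    for (id in seq_len(max(lab))) {
      ij <- which(lab == id, arr.ind = TRUE)
      if (nrow(ij) < min_blob_px) next
      extent_mmhg <- function(rows) {
        ytop <- min(rows) + ylo - 1L; ybot <- max(rows) + ylo - 1L
        abs(pixel_to_value(pmax(ytop, ax$y_px[3]), template) -
              pixel_to_value(pmin(ybot, ax$y_px[1]), template))
      }
      if (extent_mmhg(ij[, 1]) > stroke_max_mmhg) {
        # Tall component: a connecting-line stroke, possibly with the mark
        # drawn on top of it. Steep strokes cross each row in short horizontal
        # runs; a mark's core rows carry long runs. Keep only pixels in long
        # runs, then the largest contiguous row block of them -- the mark.
        keep_rows <- integer(0)
        for (rr in unique(ij[, 1])) {
          cols <- sort(ij[ij[, 1] == rr, 2])
          brk <- c(0L, which(diff(cols) != 1L), length(cols))
          if (max(diff(brk)) >= 6L) keep_rows <- c(keep_rows, rr)
        }
        if (length(keep_rows) == 0L) next          # pure stroke
        keep_rows <- sort(keep_rows)
        blk <- cumsum(c(1L, diff(keep_rows) > 2L))
        sizes <- tapply(keep_rows, blk, length)
        rows <- keep_rows[blk == as.integer(names(which.max(sizes)))]
        if (extent_mmhg(rows) > stroke_max_mmhg) next
        ij <- ij[ij[, 1] >= min(rows) & ij[, 1] <= max(rows), , drop = FALSE]
        if (nrow(ij) < min_blob_px) next
      }
      ycen <- mean(ij[, 1]) + ylo - 1L
      if (ycen > ax$y_px[1] || ycen < ax$y_px[3]) next
      comps[[length(comps) + 1L]] <- data.frame(
        area = nrow(ij), x_px = mean(ij[, 2]) + xlo - 1L, y_px = ycen)
    }
    if (length(comps) == 0L) next
    comps <- do.call(rbind, comps)
    comps <- comps[order(-comps$area), , drop = FALSE]
    comps$flag <- c("", rep("extra", nrow(comps) - 1L))
    res[[length(res) + 1L]] <- data.frame(
      eye = eye, day = lines$day[i], clock = lines$clock[i],
      value_mmhg = round(pixel_to_value(comps$y_px, template), 1),
      x_px = comps$x_px, y_px = comps$y_px,
      blob_area = comps$area, flag = comps$flag)
  }
  if (length(res) == 0L)
    return(data.frame(eye = character(), day = integer(), clock = character(),
                      value_mmhg = numeric(), x_px = numeric(), y_px = numeric(),
                      blob_area = integer(), flag = character()))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-patient IOP profile
#'
#' Container for the timestamped entries of one examination (detected or
#' simulated). Entries are sorted by day and slot; after resolution there is
#' at most one unflagged entry per (eye, slot).
#'
#' @param patient_id identifier string.
#' @param entries data frame with at least `eye`, `day`, `clock`,
#'   `value_mmhg`.
#' @param exam_date optional `Date`.
#' @return object of class `iop_profile`.
#' @export
iop_profile <- function(patient_id, entries, exam_date = NULL) {
  need <- c("eye", "day", "clock", "value_mmhg")
  if (!all(need %in% names(entries)))
    iop_error("InputError", paste("iop_profile: entries need columns",
                                  paste(need, collapse = ", ")))
  entries <- entries[order(entries$eye, entries$day,
                           match(entries$clock, SLOT_TIMES)), , drop = FALSE]
  rownames(entries) <- NULL
  structure(list(patient_id = patient_id, exam_date = exam_date,
                 entries = entries),
            class = "iop_profile")
}

#' @export
print.iop_profile <- function(x, ...) {
  cat("<iop_profile> ", x$patient_id,
      if (!is.null(x$exam_date)) paste0(" (", format(x$exam_date), ")"),
      ": ", nrow(x$entries), " entries\n", sep = "")
  print(x$entries, ...)
  invisible(x)
}

#' Write / read extraction results as CSV
#'
#' One row per entry with the schema: `patient_id`, `exam_date`, `eye`,
#' `day_index`, `clock_time`, `iop_mmhg`, `x_px`, `y_px`, `blob_area`,
#' `flag`.
#'
#' @param entries data frame from [extract_entries()] plus identification
#'   columns, or a list of such frames.
#' @param path CSV path.
#' @return `read_entries_csv` returns the data frame.
#' @export
write_entries_csv <- function(entries, path) {
  if (is.list(entries) && !is.data.frame(entries))
    entries <- do.call(rbind, entries)
  utils::write.csv(entries, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_entries_csv
#' @export
read_entries_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(clock_time = "character"))
}
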