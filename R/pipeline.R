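# Orchestration: scan -> canonical chart -> entries + header metadata -> CSV
# rows, with review flags instead of a graphical correction step.

#' Digitize one chart scan
#'
#' Runs the full pipeline: preprocessing (binarize, frame, canonical crop),
#' gridline calibration, per-eye mark extraction, and header metadata
#' (date; patient name when an OCR function is supplied). Rows with extra
#' blobs or low-confidence metadata carry review flags; a summary of flagged
#' rows replaces the interactive correction UI.
#'
#' @param scan a [raw_scan()], RGB array, or image file path.
#' @param template a [chart_template()].
#' @param days day columns to calibrate (default: template's count).
#' @param ocr_fun optional function(canonical_chart) returning header text
#'   for name extraction (external OCR engine).
#' @param classifier digit classifier for the date.
#' @param pseudonymize_names replace names by stable hashes in the output
#'   (default `TRUE`).
#' @param min_confidence date digits below this confidence flag the rows
#'   for review.
#' @param ... tuning parameters passed to [preprocess_scan()].
#' @return object of class `chart_extraction`: `entries` (CSV schema rows),
#'   `profile` (an [iop_profile()] of the resolved entries), `date`, `name`,
#'   `flags` (character vector of review notes).
#' @export
extract_chart <- function(scan, template = chart_template(), days = NULL,
                          ocr_fun = NULL, classifier = NULL,
                          pseudonymize_names = TRUE, min_confidence = 0.6, ...) {
  if (is.character(scan)) scan <- read_scan(scan)
  chart <- preprocess_scan(scan, template, ...)
  lines <- detect_time_lines(chart, days = days)
  entries <- rbind(extract_entries(chart, lines, "OD"),
                   extract_entries(chart, lines, "OS"))
  flags <- character(0)
  if (any(entries$flag == "extra"))
    flags <- c(flags, sprintf("%d extra blob(s) flagged for review",
                              sum(entries$flag == "extra")))

  exam_date <- NA; date_conf <- numeric(0)
  date_res <- tryCatch({
    if (is.null(classifier)) classifier <- default_digit_classifier()
    read_chart_date(chart, classifier)
  }, iop_error = function(e) e)
  if (inherits(date_res, "date_result")) {
    exam_date <- date_res$date
    date_conf <- date_res$confidence
    if (any(date_conf < min_confidence, na.rm = TRUE))
      flags <- c(flags, "low-confidence date digit(s)")
  } else {
    flags <- c(flags, paste("date not read:", conditionMessage(date_res)))
  }

  patient <- if (inherits(scan, "raw_scan")) scan$source_id else "unknown"
  name_res <- NULL
  if (!is.null(ocr_fun)) {
    name_res <- extract_names(ocr_fun(chart))
    if (nrow(name_res$candidates) > 0L) {
      nm <- paste(name_res$candidates$surname[1], name_res$candidates$given_name[1],
                  sep = ", ")
      patient <- if (pseudonymize_names) pseudonymize(nm) else nm
    } else flags <- c(flags, "no name candidate in OCR text")
  }

  rows <- data.frame(
    patient_id = patient,
    exam_date = if (inherits(exam_date, "Date")) as.character(exam_date) else NA_character_,
    eye = entries$eye, day_index = entries$day, clock_time = entries$clock,
    iop_mmhg = entries$value_mmhg, x_px = round(entries$x_px, 1),
    y_px = round(entries$y_px, 1), blob_area = entries$blob_area,
    flag = entries$flag)
  structure(list(
    entries = rows,
    profile = iop_profile(patient, entries[entries$flag == "", , drop = FALSE],
                          exam_date = if (inherits(exam_date, "Date")) exam_date else NULL),
    date = if (inherits(date_res, "date_result")) date_res else NULL,
    name = name_res,
    flags = flags
  ), class = "chart_extraction")
}

#' @export
print.chart_extraction <- function(x, ...) {
  cat("<chart_extraction> ", nrow(x$entries), " row(s)",
      if (length(x$flags)) paste0(", ", length(x$flags), " review flag(s)"),
      "\n", sep = "")
  if (length(x$flags)) cat(paste0("  ! ", x$flags, collapse = "\n"), "\n")
  invisible(x)
}

#' Digitize a directory of scans
#'
#' Order-independent batch extraction; per-file failures are recorded and
#' never abort the batch. Files with an existing output row set are skipped
#' when resuming.
#'
#' @param paths image files (or a directory; all PNG/TIFF/JPEG inside).
#' @param out_csv optional path: combined rows are appended per finished
#'   file, making the batch resumable.
#' @param ... passed to [extract_chart()].
#' @return list with `entries` (combined rows) and `failures` (named
#'   character vector of error messages).
#' @export
extract_charts <- function(paths, out_csv = NULL, ...) {
  if (length(paths) == 1L && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.(png|tiff?|jpe?g)$",
                        ignore.case = TRUE, full.names = TRUE)
  done <- character(0)
  if (!is.null(out_csv) && file.exists(out_csv))
    done <- unique(read_entries_csv(out_csv)$source_file)
  rows <- list(); failures <- character(0)
  for (p in sort(paths)) {
    if (basename(p) %in% done) next
    res <- tryCatch(extract_chart(p, ...), error = function(e) e)
    if (inherits(res, "error")) {
      failures[basename(p)] <- paste0(class(res)[1], ": ", conditionMessage(res))
      next
    }
    r <- res$entries
    r$source_file <- basename(p)
    rows[[length(rows) + 1L]] <- r
    if (!is.null(out_csv)) {
      first <- !file.exists(out_csv)
      utils::write.table(r, out_csv, sep = ",", row.names = FALSE,
                         col.names = first, append = !first)
    }
  }
  list(entries = if (length(rows)) do.call(rbind, rows) else NULL,
       failures = failures)
}
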