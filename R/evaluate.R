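# Extraction-accuracy evaluation: match detected entries to ground truth and
# aggregate the four accuracy metrics (false-positive rate, false-negative
# rate, mean value distance, mean relative error).

#' Match detected entries against ground truth
#'
#' An entry can only match a truth entry at the same (eye, day, slot); at
#' most one detection matches each truth entry -- the detection with the
#' nearest value wins. Unmatched detections are false positives (this
#' includes every `"extra"`-flagged blob), unmatched truth entries are false
#' negatives. Matched pairs contribute the absolute value difference.
#'
#' @param detected data frame from [extract_entries()] (any number of eyes).
#' @param truth a [ground_truth()] or a data frame with `eye`, `day`,
#'   `clock`, `value_mmhg`.
#' @return object of class `entry_matching`: data frames `matches`
#'   (truth/detected value pairs with `distance`), `false_positives`,
#'   `false_negatives`, and counts `n_detected`, `n_truth`.
#' @export
match_entries <- function(detected, truth) {
  if (inherits(truth, "ground_truth")) truth <- truth$entries
  key <- function(d) paste(d$eye, d$day, d$clock, sep = "|")
  det <- as.data.frame(detected); tru <- as.data.frame(truth)
  det$.key <- if (nrow(det)) key(det) else character(0)
  tru$.key <- if (nrow(tru)) key(tru) else character(0)
  matches <- list(); fp_idx <- integer(); fn_idx <- integer()
  used <- rep(FALSE, nrow(det))
  for (i in seq_len(nrow(tru))) {
    cand <- which(det$.key == tru$.key[i] & !used)
    if (length(cand) == 0L) { fn_idx <- c(fn_idx, i); next }
    j <- cand[which.min(abs(det$value_mmhg[cand] - tru$value_mmhg[i]))]
    used[j] <- TRUE
    matches[[length(matches) + 1L]] <- data.frame(
      eye = tru$eye[i], day = tru$day[i], clock = tru$clock[i],
      truth_mmhg = tru$value_mmhg[i], detected_mmhg = det$value_mmhg[j],
      distance = abs(det$value_mmhg[j] - tru$value_mmhg[i]))
  }
  fp <- det[!used, setdiff(names(det), ".key"), drop = FALSE]
  structure(list(
    matches = if (length(matches)) do.call(rbind, matches) else
      data.frame(eye = character(), day = integer(), clock = character(),
                 truth_mmhg = numeric(), detected_mmhg = numeric(),
                 distance = numeric()),
    false_positives = fp,
    false_negatives = tru[fn_idx, setdiff(names(tru), ".key"), drop = FALSE],
    n_detected = nrow(det), n_truth = nrow(tru)
  ), class = "entry_matching")
}

#' Aggregate matchings into the accuracy report
#'
#' One "curve" is one eye on one chart. The report carries falsely detected
#' entries per curve, missed entries per curve, the mean number of truth
#' entries per eye, and derives: `fp_rate = fp_per_curve /
#' mean_entries_per_eye`, `fn_rate = fn_per_curve / mean_entries_per_eye`,
#' and `mean_relative_error = mean_distance / mean_true_value`.
#'
#' @param matchings a single `entry_matching` or a list of them (one per
#'   chart).
#' @return object of class `eval_report`.
#' @export
compute_eval_report <- function(matchings) {
  if (inherits(matchings, "entry_matching")) matchings <- list(matchings)
  n_truth <- sum(vapply(matchings, `[[`, numeric(1), "n_truth"))
  if (n_truth == 0L)
    iop_error("EvalError", "compute_eval_report: no truth entries; rates undefined")
  # a curve = one (chart, eye) with at least one truth entry
  per_curve <- do.call(rbind, lapply(seq_along(matchings), function(k) {
    m <- matchings[[k]]
    all_eyes <- unique(c(m$matches$eye, m$false_negatives$eye, m$false_positives$eye))
    do.call(rbind, lapply(all_eyes, function(e) data.frame(
      chart = k, eye = e,
      truth = sum(m$matches$eye == e) + sum(m$false_negatives$eye == e),
      fp = sum(m$false_positives$eye == e),
      fn = sum(m$false_negatives$eye == e))))
  }))
  dists <- unlist(lapply(matchings, function(m) m$matches$distance))
  tvals <- unlist(lapply(matchings, function(m) m$matches$truth_mmhg))
  n_curves <- nrow(per_curve)
  mean_entries <- sum(per_curve$truth) / n_curves
  fp_per_curve <- sum(per_curve$fp) / n_curves
  fn_per_curve <- sum(per_curve$fn) / n_curves
  mean_distance <- if (length(dists)) mean(dists) else 0
  mean_true_value <- if (length(tvals)) mean(tvals) else NA_real_
  eval_report(n_curves, mean_entries, fp_per_curve, fn_per_curve,
              mean_distance, mean_true_value)
}

#' Build an accuracy report from per-curve counts
#'
#' The arithmetic layer of the report, usable directly from printed or
#' externally tabulated per-curve counts.
#'
#' @param n_curves number of curves evaluated.
#' @param mean_entries_per_eye mean truth entries per eye.
#' @param fp_per_curve,fn_per_curve falsely detected / missed entries per
#'   curve.
#' @param mean_distance mean absolute value difference of matched entries
#'   (mmHg).
#' @param mean_true_value mean truth value of matched entries (mmHg).
#' @return object of class `eval_report` with the derived `fp_rate`,
#'   `fn_rate` and `mean_relative_error` (fractions).
#' @export
eval_report <- function(n_curves = NA_integer_, mean_entries_per_eye = NA_real_,
                        fp_per_curve = NA_real_, fn_per_curve = NA_real_,
                        mean_distance = NA_real_, mean_true_value = NA_real_) {
  if (!is.na(mean_entries_per_eye) && mean_entries_per_eye <= 0)
    iop_error("EvalError", "eval_report: mean_entries_per_eye must be positive")
  structure(list(
    n_curves = n_curves,
    mean_entries_per_eye = mean_entries_per_eye,
    fp_per_curve = fp_per_curve,
    fn_per_curve = fn_per_curve,
    fp_rate = fp_per_curve / mean_entries_per_eye,
    fn_rate = fn_per_curve / mean_entries_per_eye,
    mean_distance = mean_distance,
    mean_true_value = mean_true_value,
    mean_relative_error = mean_distance / mean_true_value
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> over", x$n_curves, "curve(s)\n")
  cat(sprintf("  entries/eye (mean): %.2f\n", x$mean_entries_per_eye))
  cat(sprintf("  false positives:    %.4f per curve  (rate %.2f%%)\n",
              x$fp_per_curve, 100 * x$fp_rate))
  cat(sprintf("  false negatives:    %.4f per curve  (rate %.0f%%)\n",
              x$fn_per_curve, 100 * x$fn_rate))
  cat(sprintf("  mean distance:      %.4f mmHg (mean value %.2f)\n",
              x$mean_distance, x$mean_true_value))
  cat(sprintf("  mean rel. error:    %.2f%%\n", 100 * x$mean_relative_error))
  invisible(x)
}
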