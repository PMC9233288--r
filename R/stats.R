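# Clinical IOP statistics: nycthemeral summary metrics, ocular perfusion
# pressure, acrophase alignment, cutoff contingency analysis and ROC curves.

OUTPATIENT_SLOTS <- c("10:00", "14:00", "17:00")

#' Summarize a 24-hour IOP profile
#'
#' Computes T_max, T_min, T_avg (arithmetic mean), IOP_var (= T_max - T_min)
#' and the acrophase -- the slot at which the peak IOP was reached, ties
#' broken by the earliest slot. The `"outpatient"` filter restricts to the
#' office-hours slots 10:00, 14:00 and 17:00 before summarizing.
#'
#' @param profile an [iop_profile()] (or its `entries` data frame).
#' @param eye restrict to one eye (`"OD"`/`"OS"`); `NULL` uses all entries.
#' @param slot_filter `"24h"` (all slots) or `"outpatient"`.
#' @param day restrict to one day index; `NULL` uses all.
#' @return one-row data frame of class `profile_summary`: `t_max`, `t_min`,
#'   `t_avg`, `iop_var`, `acrophase`, `n_measurements`.
#' @export
summarize_profile <- function(profile, eye = NULL,
                              slot_filter = c("24h", "outpatient"), day = NULL) {
  slot_filter <- match.arg(slot_filter)
  e <- if (inherits(profile, "iop_profile")) profile$entries else profile
  if (!is.null(eye)) e <- e[e$eye == eye, , drop = FALSE]
  if (!is.null(day)) e <- e[e$day == day, , drop = FALSE]
  if ("flag" %in% names(e)) e <- e[e$flag %in% c("", NA), , drop = FALSE]
  if (slot_filter == "outpatient")
    e <- e[e$clock %in% OUTPATIENT_SLOTS, , drop = FALSE]
  if (nrow(e) == 0L)
    iop_error("EmptyProfile", "summarize_profile: no entries after filtering")
  ord <- order(e$day, match(e$clock, SLOT_TIMES))
  e <- e[ord, , drop = FALSE]
  v <- e$value_mmhg
  peak <- which.max(v)   # which.max takes the first (earliest slot) on ties
  out <- data.frame(t_max = max(v), t_min = min(v), t_avg = mean(v),
                    iop_var = max(v) - min(v), acrophase = e$clock[peak],
                    n_measurements = length(v))
  class(out) <- c("profile_summary", class(out))
  out
}

#' Mean ocular perfusion pressure
#'
#' MAP is estimated as diastolic plus one-third of the pulse pressure;
#' MOPP as two-thirds of the difference between MAP and the mean IOP:
#' `MOPP = (2/3) * (MAP - T_avg)`.
#'
#' @param systolic,diastolic brachial blood pressure, mmHg (vectorized).
#' @param t_avg mean IOP, mmHg.
#' @return data frame of class `perfusion_record`: `systolic`, `diastolic`,
#'   `map`, `mopp`.
#' @export
compute_mopp <- function(systolic, diastolic, t_avg) {
  if (any(diastolic <= 0) || any(diastolic >= systolic))
    iop_error("InputError", "compute_mopp: need 0 < diastolic < systolic")
  map <- diastolic + (systolic - diastolic) / 3
  out <- data.frame(systolic = systolic, diastolic = diastolic, map = map,
                    mopp = (2 / 3) * (map - t_avg))
  class(out) <- c("perfusion_record", class(out))
  out
}

#' Align profiles by acrophase and average per slot
#'
#' Circularly shifts each profile's slot sequence so every acrophase lands
#' on the reference slot, then averages per slot. Profiles with fewer than
#' two slots are skipped with a warning.
#'
#' @param profiles list of [iop_profile()] (single-day, one eye each).
#' @param reference_slot slot at which all peaks are aligned.
#' @return data frame: `clock`, `mean_mmhg`, `sd_mmhg`, `n`.
#' @export
align_acrophases <- function(profiles, reference_slot = "10:00") {
  ref <- match(reference_slot, SLOT_TIMES)
  if (is.na(ref)) iop_error("InputError", "align_acrophases: unknown reference slot")
  acc <- matrix(NA_real_, length(profiles), 5L)
  kept <- 0L
  for (p in profiles) {
    e <- if (inherits(p, "iop_profile")) p$entries else p
    e <- e[match(SLOT_TIMES, e$clock), , drop = FALSE]
    v <- e$value_mmhg
    if (sum(!is.na(v)) < 2L) {
      warning("align_acrophases: skipping a profile with < 2 slots")
      next
    }
    peak <- which.max(v)
    shift <- (seq_len(5L) - 1L + (peak - ref)) %% 5L + 1L
    kept <- kept + 1L
    acc[kept, ] <- v[shift]
  }
  if (kept == 0L) iop_error("EmptyProfile", "align_acrophases: no usable profiles")
  acc <- acc[seq_len(kept), , drop = FALSE]
  data.frame(clock = SLOT_TIMES,
             mean_mmhg = colMeans(acc, na.rm = TRUE),
             sd_mmhg = apply(acc, 2, stats::sd, na.rm = TRUE),
             n = colSums(!is.na(acc)))
}

#' Cutoff contingency analysis
#'
#' Dichotomizes a summary statistic at a cutoff (strictly greater than the
#' cutoff means test-positive), crosses it with the progression labels, and
#' reports the 2 x 2 table with sensitivity = TP / (TP + FN) and
#' specificity = TN / (TN + FP).
#'
#' @param summaries data frame of profile summaries (one row per patient,
#'   from [summarize_profile()]), or a list of profiles (then summarized
#'   with `slot_set`).
#' @param labels logical/0-1 vector of progression labels, aligned by row.
#' @param cutoff threshold in mmHg.
#' @param statistic `"t_max"` or `"iop_var"`.
#' @param slot_set `"24h"` or `"outpatient"`; applied when `summaries` is a
#'   list of profiles.
#' @return object of class `diagnostic_result` with the counts and rates.
#' @export
cutoff_contingency <- function(summaries, labels, cutoff,
                               statistic = c("t_max", "iop_var"),
                               slot_set = c("24h", "outpatient")) {
  statistic <- match.arg(statistic)
  slot_set <- match.arg(slot_set)
  if (is.list(summaries) && !is.data.frame(summaries))
    summaries <- do.call(rbind, lapply(summaries, summarize_profile,
                                       slot_filter = slot_set))
  if (nrow(summaries) != length(labels))
    iop_error("InputError", "cutoff_contingency: summaries and labels misaligned")
  score <- summaries[[statistic]]
  pos <- score > cutoff
  lab <- as.logical(labels)
  tp <- sum(pos & lab); fn <- sum(!pos & lab)
  fp <- sum(pos & !lab); tn <- sum(!pos & !lab)
  sens <- if (tp + fn == 0) NaN else tp / (tp + fn)
  spec <- if (tn + fp == 0) NaN else tn / (tn + fp)
  if (is.nan(sens) || is.nan(spec))
    warning("cutoff_contingency: all labels identical; a rate is undefined")
  structure(list(cutoff = cutoff, statistic = statistic, slot_set = slot_set,
                 tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = sens, specificity = spec,
                 n = length(labels)),
            class = "diagnostic_result")
}

#' @export
print.diagnostic_result <- function(x, ...) {
  cat(sprintf("<diagnostic_result> %s > %g mmHg (%s slots), n = %d\n",
              x$statistic, x$cutoff, x$slot_set, x$n))
  cat(sprintf("  TP %d  FN %d  FP %d  TN %d\n", x$tp, x$fn, x$fp, x$tn))
  cat(sprintf("  sensitivity %.2f  specificity %.2f\n",
              x$sensitivity, x$specificity))
  invisible(x)
}

#' Receiver operating characteristic curve
#'
#' Sweeps every distinct score as a threshold (ties grouped into one step;
#' test-positive means score strictly greater than the threshold), collects
#' (1 - specificity, sensitivity) points from (0,0) to (1,1), and computes
#' the AUC by the trapezoid rule.
#'
#' @param scores numeric scores (higher = more test-positive).
#' @param labels 0/1 or logical outcome labels.
#' @param exclude_scores_below optionally drop observations whose score is
#'   below this value before the sweep (used to exclude nycthemeral
#'   variations under 5 mmHg).
#' @return object of class `roc_curve`: `points` (data frame `fpr`, `tpr`,
#'   `threshold`) and `auc`.
#' @export
roc_curve <- function(scores, labels, exclude_scores_below = NULL) {
  lab <- as.logical(labels)
  if (!is.null(exclude_scores_below)) {
    keep <- scores >= exclude_scores_below
    scores <- scores[keep]; lab <- lab[keep]
  }
  np <- sum(lab); nn <- sum(!lab)
  if (np == 0L || nn == 0L)
    iop_error("ROCUndefined", "roc_curve: need at least one positive and one negative")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores > t & lab) / np, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores > t & !lab) / nn, numeric(1))
  pts <- data.frame(threshold = c(Inf, thr),
                    fpr = c(0, fpr), tpr = c(0, tpr))
  # ensure terminal point (1,1): the lowest threshold classifies all positive
  if (pts$fpr[nrow(pts)] < 1 || pts$tpr[nrow(pts)] < 1)
    pts <- rbind(pts, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc, n_pos = np, n_neg = nn),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d thresholds, %d pos / %d neg, AUC = %.3f\n",
              nrow(x$points), x$n_pos, x$n_neg, x$auc))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "l",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 2, col = "gray")
  invisible(x)
}
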