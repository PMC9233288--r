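# Round-trip batch: simulate per-patient truth values, render each chart,
# digitize it, and match against truth. Right-eye values come from the cohort
# generator; left-eye values are offset by at least 2 mmHg so the two pens
# never draw on top of each other (a covered mark is unrecoverable ink, not
# an extraction failure).

roundtrip_batch <- function(n, noisy, seed) {
  sim <- simulate_cohort(cohort_config(n = n, seed = seed))
  tpl <- tpl_test
  ms <- vector("list", n)
  max_err <- 0
  for (i in seq_len(n)) {
    vals_od <- sim$profiles[[i]]$entries$value_mmhg
    set.seed(seed * 1000 + i)
    off <- sample(c(-1, 1), 5, replace = TRUE) * runif(5, 2, 5)
    vals_os <- round(pmin(pmax(vals_od + off, 1), 60), 1)
    tr <- ground_truth(values_od = vals_od, values_os = vals_os,
                       patient_id = sprintf("P%03d", i), template = tpl)
    cfg <- if (noisy) {
      render_config(seed = seed * 1000 + i, noise_sigma = 8,
                    rotation_deg = c(-3, 3), jitter_px = 2, join_lines = TRUE)
    } else {
      render_config(seed = seed * 1000 + i)
    }
    scan <- render_chart(tr, cfg, tpl)
    chart <- preprocess_scan(scan, tpl)
    lines <- detect_time_lines(chart, days = 1)
    det <- rbind(extract_entries(chart, lines, "OD"),
                 extract_entries(chart, lines, "OS"))
    m <- match_entries(det, attr(scan, "truth"))
    if (nrow(m$matches)) max_err <- max(max_err, max(m$matches$distance))
    ms[[i]] <- m
  }
  rep <- compute_eval_report(ms)
  list(report = rep, max_err = max_err,
       recall = 1 - rep$fn_rate, n = n)
}
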