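# Clinical IOP statistics.

mk_profile <- function(values, clock = SLOT_TIMES, eye = "OD")
  iop_profile("T", data.frame(eye = eye, day = 0L, clock = clock,
                              value_mmhg = values))

test_that("profile summaries compute the nycthemeral metrics directly", {
  s <- summarize_profile(mk_profile(c(15, 18, 17, 14, 16)))
  expect_equal(s$t_max, 18); expect_equal(s$t_min, 14)
  expect_equal(s$t_avg, 16); expect_equal(s$iop_var, 4)
  expect_identical(s$acrophase, "14:00")
  # constant profile: zero variation, earliest-slot tie rule
  s2 <- summarize_profile(mk_profile(rep(16, 5)))
  expect_equal(s2$iop_var, 0)
  expect_identical(s2$acrophase, "10:00")
})

test_that("the outpatient filter keeps only office-hour slots", {
  s <- summarize_profile(mk_profile(c(15, 18, 17, 14, 16)),
                         slot_filter = "outpatient")
  expect_equal(s$n_measurements, 3L)
  expect_equal(s$t_max, 18); expect_equal(s$t_min, 15)
  expect_error(summarize_profile(mk_profile(c(14, 16), c("21:00", "00:00")),
                                 slot_filter = "outpatient"),
               class = "EmptyProfile")
})

test_that("summaries equal brute-force max/min/mean on random profiles", {
  set.seed(70)
  for (i in 1:25) {
    n <- sample(2:5, 1)
    cl <- sort(sample(seq_along(SLOT_TIMES), n))
    v <- round(runif(n, 5, 45), 1)
    s <- summarize_profile(mk_profile(v, SLOT_TIMES[cl]))
    expect_equal(s$t_max, max(v)); expect_equal(s$t_min, min(v))
    expect_equal(s$t_avg, mean(v)); expect_equal(s$iop_var, max(v) - min(v))
    expect_identical(s$acrophase, SLOT_TIMES[cl][which.max(v)])
    expect_true(s$t_min <= s$t_avg && s$t_avg <= s$t_max)
  }
})

test_that("perfusion pressure follows the MAP and two-thirds formulas", {
  r <- compute_mopp(120, 80, 15)
  expect_equal(r$map, 93 + 1 / 3, tolerance = 1e-9)
  expect_equal(r$mopp, (2 / 3) * (r$map - 15), tolerance = 1e-9)
  expect_equal(round(r$mopp, 2), 52.22)
  # T_avg = MAP gives zero perfusion pressure
  expect_equal(compute_mopp(120, 80, 93 + 1 / 3)$mopp, 0, tolerance = 1e-9)
  # linearity: +3 mmHg IOP costs exactly 2 mmHg of perfusion
  expect_equal(compute_mopp(120, 80, 18)$mopp - compute_mopp(120, 80, 15)$mopp,
               -2, tolerance = 1e-9)
  expect_error(compute_mopp(80, 120, 15), class = "InputError")
})

test_that("acrophase alignment shifts peaks to the reference slot", {
  # all profiles already peak at 10:00: alignment is the identity
  ps <- list(mk_profile(c(20, 15, 14, 13, 16)), mk_profile(c(22, 18, 15, 14, 17)))
  al <- align_acrophases(ps)
  expect_equal(al$mean_mmhg, colMeans(rbind(c(20, 15, 14, 13, 16),
                                            c(22, 18, 15, 14, 17))))
  # construction guarantee: aligned mean attains its max at the reference slot
  sim <- simulate_cohort(cohort_config(n = 150, seed = 33))
  al2 <- align_acrophases(sim$profiles)
  expect_identical(al2$clock[which.max(al2$mean_mmhg)], "10:00")
  # aligned peak exceeds the observed (unaligned) per-slot peak mean
  vals <- t(vapply(sim$profiles, function(p)
    p$entries$value_mmhg[match(SLOT_TIMES, p$entries$clock)], numeric(5)))
  expect_gt(max(al2$mean_mmhg), max(colMeans(vals)))
  expect_warning(align_acrophases(list(mk_profile(15, "10:00"),
                                       mk_profile(c(20, 15, 14, 13, 16)))),
                 "< 2 slots")
})

test_that("cutoff contingency fills the 2x2 table and rates", {
  # perfect classifier
  d <- cutoff_contingency(data.frame(t_max = c(30, 28, 12, 10)),
                          c(1, 1, 0, 0), 22, "t_max")
  expect_equal(d$sensitivity, 1); expect_equal(d$specificity, 1)
  # worked 4-patient example
  d2 <- cutoff_contingency(data.frame(t_max = c(23, 14, 25, 16)),
                           c(1, 1, 0, 0), 22, "t_max")
  expect_equal(c(d2$tp, d2$fn, d2$fp, d2$tn), c(1, 1, 1, 1))
  expect_equal(d2$sensitivity, 0.5); expect_equal(d2$specificity, 0.5)
  expect_equal(d2$tp + d2$fn + d2$fp + d2$tn, d2$n)
  # strict inequality at the cutoff
  d3 <- suppressWarnings(
    cutoff_contingency(data.frame(t_max = c(22, 23)), c(1, 1), 22, "t_max"))
  expect_equal(d3$tp, 1); expect_equal(d3$fn, 1)
  expect_warning(cutoff_contingency(data.frame(t_max = c(22, 23)), c(1, 1),
                                    22, "t_max"), "undefined")
})

test_that("outpatient summaries recompute T_max before thresholding", {
  # peak at midnight: 24h and outpatient T_max disagree across the cutoff
  ps <- list(mk_profile(c(14, 15, 14, 13, 24)), mk_profile(c(14, 13, 12, 13, 14)))
  d24 <- cutoff_contingency(ps, c(1, 0), 22, "t_max", slot_set = "24h")
  dop <- cutoff_contingency(ps, c(1, 0), 22, "t_max", slot_set = "outpatient")
  expect_equal(d24$tp, 1)
  expect_equal(dop$tp, 0)
})

test_that("ROC sweep has the canonical properties and matches pROC", {
  expect_equal(roc_curve(c(1, 1, 0, 0), c(1, 1, 0, 0))$auc, 1)
  set.seed(80)
  scores <- rnorm(1000); labels <- rbinom(1000, 1, 0.4)
  r <- roc_curve(scores, labels)
  expect_lt(abs(r$auc - 0.5), 0.05)
  # reversal symmetry
  expect_equal(roc_curve(-scores, labels)$auc, 1 - r$auc, tolerance = 1e-12)
  # monotone from (0,0) to (1,1)
  expect_true(all(diff(r$points$fpr) >= 0) && all(diff(r$points$tpr) >= 0))
  expect_equal(unlist(r$points[1, c("fpr", "tpr")]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(r$points[nrow(r$points), c("fpr", "tpr")]),
               c(fpr = 1, tpr = 1))
  skip_if_not_installed("pROC")
  pr <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-9)
  # tied scores grouped into one threshold step
  r2 <- roc_curve(c(3, 3, 2, 2, 1), c(1, 1, 0, 1, 0))
  pr2 <- pROC::roc(c(1, 1, 0, 1, 0), c(3, 3, 2, 2, 1), quiet = TRUE, direction = "<")
  expect_equal(r2$auc, as.numeric(pROC::auc(pr2)), tolerance = 1e-9)
})

test_that("the low-variation exclusion restricts the ROC sample", {
  scores <- c(2, 4, 6, 8, 10); labels <- c(0, 1, 0, 1, 1)
  r <- roc_curve(scores, labels, exclude_scores_below = 5)
  expect_equal(r$n_pos + r$n_neg, 3L)
  expect_error(roc_curve(c(1, 2), c(1, 1)), class = "ROCUndefined")
})
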