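# Gridline calibration, color masks and mark-to-value extraction.

test_that("a clean single-day chart yields one line per slot at template x", {
  cc <- make_clean_chart(seed = 41)
  lines <- detect_time_lines(cc$chart, days = 1)
  slots <- tpl_test$time_slots[tpl_test$time_slots$day == 0, ]
  expect_equal(nrow(lines), 5L)
  expect_identical(lines$clock, SLOT_TIMES)
  expect_lt(max(abs(lines$x_px - slots$x)), 3)
})

test_that("a drawn horizontal reference line does not disturb calibration", {
  cc <- make_clean_chart(seed = 42)
  y20 <- round(value_to_pixel(20, tpl_test))
  px <- cc$chart$pixels
  px[(y20 - 1):(y20 + 1), 100:1180, ] <- 0.1   # dark 20-mmHg rule
  chart <- structure(list(pixels = px, template = tpl_test, source_id = "x"),
                     class = "canonical_chart")
  lines <- detect_time_lines(chart, days = 1)
  expect_equal(nrow(lines), 5L)
})

test_that("a blank frame raises CalibrationError", {
  W <- unname(tpl_test$canonical_size["width"])
  H <- unname(tpl_test$canonical_size["height"])
  px <- array(1, c(H, W, 3))
  px[1:3, , ] <- 0; px[(H - 2):H, , ] <- 0; px[, 1:3, ] <- 0; px[, (W - 2):W, ] <- 0
  chart <- structure(list(pixels = px, template = tpl_test, source_id = "blank"),
                     class = "canonical_chart")
  expect_error(detect_time_lines(chart, days = 1), class = "CalibrationError")
})

test_that("color masks separate the eyes and ignore achromatic ink", {
  cc <- make_clean_chart(values_od = c(15, 18, 17, 14, 16),
                         values_os = c(20, 22, 19, 21, 20), seed = 43)
  od <- color_mask(cc$chart, "OD"); os <- color_mask(cc$chart, "OS")
  expect_false(any(od & os))            # disjoint by construction
  expect_gt(sum(od), 0); expect_gt(sum(os), 0)
  # blue-only chart: OS mask empty, OD mask sits at the drawn marks
  cb <- make_clean_chart(seed = 44)
  expect_equal(sum(color_mask(cb$chart, "OS")), 0)
  odb <- color_mask(cb$chart, "OD")
  ij <- which(odb, arr.ind = TRUE)
  tr <- cb$truth$entries
  d2 <- outer(ij[, 1], tr$y_px, "-")^2 + outer(ij[, 2], tr$x_px, "-")^2
  expect_lt(max(sqrt(apply(d2, 1, min))), 6)  # all mask pixels at mark blobs
  # grayscale chart: both masks empty
  gray3 <- array(rep(to_gray(cb$chart$pixels), 3),
                 dim = dim(cb$chart$pixels))
  expect_equal(sum(color_mask(gray3, "OD")), 0)
  expect_equal(sum(color_mask(gray3, "OS")), 0)
})

test_that("noiseless extraction recovers every entry to within quantization", {
  vals <- c(15, 18, 17, 14, 16)
  cc <- make_clean_chart(values_od = vals, seed = 45)
  lines <- detect_time_lines(cc$chart, days = 1)
  ent <- extract_entries(cc$chart, lines, "OD")
  expect_equal(nrow(ent), 5L)
  expect_true(all(ent$flag == ""))
  expect_lt(max(abs(ent$value_mmhg - vals)), 0.5)
  expect_equal(nrow(extract_entries(cc$chart, lines, "OS")), 0L)
})

test_that("connecting polyline strokes are rejected by the vertical-extent rule", {
  vals <- c(12, 26, 13, 27, 14)   # steep joins crossing gridlines
  cc <- make_clean_chart(values_od = vals, seed = 46, join_lines = TRUE)
  lines <- detect_time_lines(cc$chart, days = 1)
  ent <- extract_entries(cc$chart, lines, "OD")
  keep <- ent[ent$flag == "", ]
  expect_equal(nrow(keep), 5L)
  expect_lt(max(abs(keep$value_mmhg - vals)), 1.0)
})

test_that("entries never originate from the other eye's mask", {
  cc <- make_clean_chart(values_od = c(15, 18, 17, 14, 16),
                         values_os = c(30, 31, 32, 33, 34), seed = 47)
  lines <- detect_time_lines(cc$chart, days = 1)
  od <- extract_entries(cc$chart, lines, "OD")
  os_mask <- color_mask(cc$chart, "OS")
  hits <- os_mask[cbind(round(od$y_px), round(od$x_px))]
  expect_false(any(hits))
  expect_lt(max(abs(od$value_mmhg - c(15, 18, 17, 14, 16))), 0.5)
  os <- extract_entries(cc$chart, lines, "OS")
  expect_lt(max(abs(os$value_mmhg - c(30, 31, 32, 33, 34))), 0.5)
})

test_that("values are reported at sub-unit (0.1 mmHg) resolution", {
  cc <- make_clean_chart(values_od = c(15.5, 18.2, 17.0, 14.8, 16.3), seed = 48)
  lines <- detect_time_lines(cc$chart, days = 1)
  ent <- extract_entries(cc$chart, lines, "OD")
  expect_lt(max(abs(ent$value_mmhg - c(15.5, 18.2, 17.0, 14.8, 16.3))), 0.5)
  expect_true(any(ent$value_mmhg %% 1 != 0))
})

test_that("profiles sort entries and expose them per eye and slot", {
  p <- iop_profile("X", data.frame(
    eye = c("OD", "OD"), day = c(0L, 0L), clock = c("14:00", "10:00"),
    value_mmhg = c(18, 15)))
  expect_identical(p$entries$clock, c("10:00", "14:00"))
  f <- withr::local_tempfile(fileext = ".csv")
  rows <- data.frame(patient_id = "X", exam_date = "2018-03-12", eye = "OD",
                     day_index = 0L, clock_time = SLOT_TIMES,
                     iop_mmhg = c(15, 18, 17, 14, 16), x_px = 1, y_px = 1,
                     blob_area = 40L, flag = "")
  write_entries_csv(rows, f)
  back <- read_entries_csv(f)
  expect_identical(back$clock_time, SLOT_TIMES)  # "00:00" survives as text
  expect_equal(back$iop_mmhg, rows$iop_mmhg)
})
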