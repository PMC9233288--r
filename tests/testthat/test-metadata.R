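# Header metadata: digit segmentation, classification, date assembly, names.

test_that("date segmentation finds 8 digits and 2 delimiters in order", {
  chart <- make_date_chart(as.Date("2018-03-12"), seed = 1)
  regs <- segment_date_digits(chart)
  roles <- vapply(regs, `[[`, character(1), "role")
  expect_equal(sum(roles == "digit"), 8L)
  expect_equal(sum(roles == "delimiter"), 2L)
  expect_identical(roles, c("digit", "digit", "delimiter", "digit", "digit",
                            "delimiter", rep("digit", 4)))
  xs <- vapply(regs, function(r) unname(r$box["x1"]), numeric(1))
  expect_true(all(diff(xs) > 0))
})

test_that("an empty date field raises DateNotFound", {
  W <- unname(tpl_test$canonical_size["width"])
  H <- unname(tpl_test$canonical_size["height"])
  blank <- structure(list(pixels = array(1, c(H, W, 3)), template = tpl_test,
                          source_id = "blank"), class = "canonical_chart")
  expect_error(segment_date_digits(blank), class = "DateNotFound")
})

test_that("touching digits are flagged as a double-width region", {
  chart <- make_date_chart(as.Date("2018-03-12"), seed = 2)
  # smudge the two year digits "2" and "0" into one touching component
  regs <- segment_date_digits(chart)
  b1 <- regs[[7]]$box; b2 <- regs[[8]]$box
  h <- b1["y2"] - b1["y1"]
  rows <- round(b1["y1"] + h / 3):round(b1["y1"] + 2 * h / 3)
  chart$pixels[rows, round(mean(b1[c("x1", "x2")])):round(mean(b2[c("x1", "x2")])), ] <- 0.15
  regs2 <- segment_date_digits(chart)
  warn <- vapply(regs2, `[[`, character(1), "warning")
  expect_equal(sum(warn == "double-width"), 1L)
  expect_equal(sum(vapply(regs2, `[[`, character(1), "role") == "digit"), 7L)
})

test_that("the default classifier is accurate and returns true probabilities", {
  clf <- default_digit_classifier()
  set.seed(90)
  n <- 500; hits <- 0
  for (i in seq_len(n)) {
    d <- sample(0:9, 1)
    g <- render_digit(d, height = sample(24:40, 1),
                      rotation_deg = runif(1, -10, 10),
                      variant = sample(c("a", "b"), 1),
                      noise_sd = runif(1, 0, 0.1), widen = runif(1, 0.9, 1.1))
    res <- classify_digit(g > 0.5, clf)
    hits <- hits + (res$digit == d)
    if (i <= 25) {
      p <- attr(res, "distribution")
      expect_true(all(p >= 0 & p <= 1))
      expect_equal(sum(p), 1, tolerance = 1e-6)
    }
  }
  expect_gte(hits / n, 0.95)
  # clean render of the training font: confident and correct
  res <- classify_digit(render_digit(7, 32) > 0.5)
  expect_identical(res$digit, 7L)
  expect_gt(res$confidence, 0.9)
  expect_error(classify_digit(matrix(0, 28, 28)), class = "ClassificationError")
})

test_that("digit groups assemble into legal dates with year expansion", {
  roles10 <- c("digit", "digit", "delimiter", "digit", "digit", "delimiter",
               rep("digit", 4))
  r <- parse_date(fake_regions(roles10), c(1, 2, 0, 3, 2, 0, 1, 8))
  expect_equal(r$date, as.Date("2018-03-12"))
  expect_error(parse_date(fake_regions(roles10), c(3, 1, 0, 2, 2, 0, 1, 9)),
               class = "DateInvalid")   # Feb 31
  roles8 <- c("digit", "digit", "delimiter", "digit", "digit", "delimiter",
              "digit", "digit")
  r2 <- parse_date(fake_regions(roles8), c(0, 5, 1, 1, 1, 7))
  expect_equal(r2$date, as.Date("2017-11-05"))
  r3 <- parse_date(fake_regions(roles8), c(0, 5, 1, 1, 6, 5))
  expect_equal(r3$date, as.Date("1965-11-05"))
  expect_error(parse_date(fake_regions(roles10), c(1, 2, 0, 3, 1, 8, 7, 0)),
               class = "DateInvalid")   # year 1870 implausible
})

test_that("full date round-trip succeeds on at least 90% of clean headers", {
  n <- 200; ok <- 0
  dates <- as.Date("1995-01-01") + seq(0, by = 53, length.out = n)
  for (i in seq_len(n)) {
    got <- tryCatch(read_chart_date(make_date_chart(dates[i], seed = 1000 + i))$date,
                    error = function(e) as.Date(NA))
    ok <- ok + identical(got, dates[i])
  }
  expect_gte(ok / n, 0.9)
})

test_that("delimiter classification never consumes more than two regions", {
  for (s in 1:10) {
    regs <- segment_date_digits(make_date_chart(as.Date("2019-12-31") - 37 * s,
                                                seed = s))
    roles <- vapply(regs, `[[`, character(1), "role")
    expect_lte(sum(roles == "delimiter"), 2L)
  }
})

test_that("name extraction matches capitalized pairs, with diacritics", {
  r <- extract_names("Mustermann, Erika  geb. 01.02.1950")
  expect_equal(r$candidates$surname, "Mustermann")
  expect_equal(r$candidates$given_name, "Erika")
  expect_equal(nrow(extract_names("IOD-TAGESPROFIL Station 3")$candidates), 0L)
  r2 <- extract_names("Öztürk, Ayşe")
  expect_equal(r2$candidates$surname, "Öztürk")
  expect_equal(r2$candidates$given_name, "Ayşe")
  # reading order preserved over multiple matches
  r3 <- extract_names("Meier, Hans ... Schulz, Anna")
  expect_identical(r3$candidates$surname, c("Meier", "Schulz"))
})

test_that("pseudonyms are stable, short and distinct", {
  p <- pseudonymize(c("Mustermann, Erika", "Mustermann, Erika", "Meier, Hans"))
  expect_identical(p[1], p[2])
  expect_false(p[1] == p[3])
  expect_true(all(nchar(p) == 12))
})
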