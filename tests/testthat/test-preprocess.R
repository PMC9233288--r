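# Binarization, frame detection and canonical cropping.

test_that("adaptive threshold leaves a constant image all background", {
  img <- matrix(0.5, 50, 50)
  expect_false(any(binarize_adaptive(img, window = 27, offset = 10)))
})

test_that("adaptive threshold matches the brute-force Gaussian-window oracle", {
  img <- matrix(1, 9, 9); img[5, 5] <- 0
  got <- binarize_adaptive(img, window = 5, offset = 10)
  expect_identical(got, oracle_binarize(img, 5, 10))
  expect_true(got[5, 5])          # the lone dark pixel is foreground
  expect_lte(sum(got), 1L)        # and nothing else can fall below mean - C

  set.seed(11)
  for (i in 1:8) {
    h <- sample(8:24, 1); w <- sample(8:24, 1)
    win <- sample(c(3, 5, 7), 1)
    img <- matrix(runif(h * w), h, w)
    expect_identical(binarize_adaptive(img, win, 10), oracle_binarize(img, win, 10))
  }
})

test_that("binarization defaults and input contracts", {
  expect_identical(formals(binarize_adaptive)$window, 27L)
  expect_identical(formals(binarize_adaptive)$offset, 10)
  expect_error(binarize_adaptive(matrix(0.5, 5, 5), window = 4), class = "InputError")
  expect_error(binarize_adaptive(matrix(numeric(0), 0, 0)), class = "InputError")
})

test_that("frame detection recovers a drawn rectangle regardless of interior", {
  img <- matrix(1, 760, 1000)
  img[80:82, 100:900] <- 0; img[678:680, 100:900] <- 0
  img[80:680, 100:102] <- 0; img[80:680, 898:900] <- 0
  img[300:420, 400:520] <- 0   # interior content must not matter
  fr <- find_main_frame(img < 0.5)
  truth <- cbind(x = c(100, 900, 900, 100), y = c(80, 80, 680, 680))
  expect_lt(max(abs(unclass(fr)[, 1:2] - truth)), 2)
})

test_that("frame detection completes a cut-off corner from the edge lines", {
  img <- matrix(1, 760, 1000)
  img[80:82, 100:900] <- 0; img[678:680, 100:900] <- 0
  img[80:680, 100:102] <- 0; img[80:680, 898:900] <- 0
  img[80:140, 840:900] <- 1   # erase the top-right corner region
  fr <- find_main_frame(img < 0.5)
  truth <- cbind(x = c(100, 900, 900, 100), y = c(80, 80, 680, 680))
  expect_lt(max(sqrt(rowSums((unclass(fr)[, 1:2] - truth)^2))), 5)
})

test_that("frame detection is robust to small rotations", {
  tr <- ground_truth(values_od = c(15, 18, 17, 14, 16), template = tpl_test)
  for (deg in c(-5, -3, 3, 5)) {
    scan <- render_chart(tr, render_config(seed = 20 + deg, rotation_deg = deg),
                         tpl_test)
    fr <- find_main_frame(binarize_adaptive(to_gray(scan)))
    # true corners: canonical rectangle corners rotated about the page center
    d <- dim(scan$pixels); m <- 60
    W <- unname(tpl_test$canonical_size["width"])
    H <- unname(tpl_test$canonical_size["height"])
    ctr <- c((d[2] + 1) / 2, (d[1] + 1) / 2)
    th <- -deg * pi / 180
    pts <- cbind(c(1, W, W, 1) + m, c(1, 1, H, H) + m)
    truth <- cbind(ctr[1] + cos(th) * (pts[, 1] - ctr[1]) - sin(th) * (pts[, 2] - ctr[2]),
                   ctr[2] + sin(th) * (pts[, 1] - ctr[1]) + cos(th) * (pts[, 2] - ctr[2]))
    expect_lt(max(sqrt(rowSums((unclass(fr)[, 1:2] - truth)^2))), 5)
    expect_true(all(abs(attr(fr, "angles") - 90) <= 10))
  }
})

test_that("frame errors carry the stage-specific condition classes", {
  expect_error(find_main_frame(matrix(FALSE, 100, 100)), class = "FrameNotFound")
  # small blob: largest contour below the minimum frame fraction
  img <- matrix(FALSE, 200, 200); img[90:110, 90:110] <- TRUE
  expect_error(find_main_frame(img), class = "FrameNotFound")
  # a triangle passes the size gate but is no rectangle
  img2 <- matrix(FALSE, 300, 300)
  for (i in 0:200) img2[40 + i, 40:(40 + i)] <- TRUE
  expect_error(find_main_frame(img2), class = "FrameNotRectangular")
})

test_that("cropping the full canvas is the identity", {
  cc <- make_clean_chart(seed = 31)
  W <- unname(tpl_test$canonical_size["width"])
  H <- unname(tpl_test$canonical_size["height"])
  quad <- cbind(x = c(1, W, W, 1), y = c(1, 1, H, H))
  again <- crop_to_canonical(cc$chart, quad, tpl_test)
  expect_equal(again$pixels, cc$chart$pixels, tolerance = 1e-12)
  expect_identical(dim(again$pixels), c(H, W, 3L))
})

test_that("canonical crops agree across rotation and resolution", {
  tr <- ground_truth(values_od = c(15, 18, 17, 14, 16), template = tpl_test)
  scan <- render_chart(tr, render_config(seed = 5, rotation_deg = 3), tpl_test)
  hi <- raw_scan(resize_image(scan$pixels, 1.4), "hi-res")
  l1 <- detect_time_lines(preprocess_scan(scan, tpl_test), days = 1)
  l2 <- detect_time_lines(preprocess_scan(hi, tpl_test), days = 1)
  expect_equal(nrow(l1), 5L)
  expect_lt(max(abs(l1$x_px - l2$x_px)), 2)
  slots <- tpl_test$time_slots[tpl_test$time_slots$day == 0, ]
  expect_lt(max(abs(l1$x_px - slots$x)), 2)
  expect_error(crop_to_canonical(scan, cbind(x = c(1, 5, 5, 1), y = c(1, 1, 5, 5)),
                                 tpl_test), class = "FrameNotFound")
})
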