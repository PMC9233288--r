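# Digit glyph rendering. Digits are drawn from compact 5 x 7 dot-matrix
# bitmaps (two stylistic variants), upscaled and perturbed (rotation, scale
# jitter, pixel noise) to emulate handwritten header digits. The same
# renderer supplies training data for the default digit classifier, so the
# test suite needs no external data set.

.font_rows <- list(
  a = list(
    `0` = c("01110","10001","10011","10101","11001","10001","01110"),
    `1` = c("00100","01100","00100","00100","00100","00100","01110"),
    `2` = c("01110","10001","00001","00010","00100","01000","11111"),
    `3` = c("11111","00010","00100","00010","00001","10001","01110"),
    `4` = c("00010","00110","01010","10010","11111","00010","00010"),
    `5` = c("11111","10000","11110","00001","00001","10001","01110"),
    `6` = c("00110","01000","10000","11110","10001","10001","01110"),
    `7` = c("11111","00001","00010","00100","01000","01000","01000"),
    `8` = c("01110","10001","10001","01110","10001","10001","01110"),
    `9` = c("01110","10001","10001","01111","00001","00010","01100")),
  b = list(
    `0` = c("01110","10001","10001","10001","10001","10001","01110"),
    `1` = c("00100","00100","00100","00100","00100","00100","00100"),
    `2` = c("01110","10001","00001","00110","01000","10000","11111"),
    `3` = c("01110","10001","00001","00110","00001","10001","01110"),
    `4` = c("00010","00110","01010","10010","11111","00010","00010"),
    `5` = c("11111","10000","11110","00001","00001","00001","11110"),
    `6` = c("01110","10000","10000","11110","10001","10001","01110"),
    `7` = c("11111","00001","00010","00100","00100","01000","01000"),
    `8` = c("01110","10001","10001","01110","10001","10001","01110"),
    `9` = c("01110","10001","10001","01111","00001","00001","01110"))
)

digit_bitmap <- function(digit, variant = "a") {
  rows <- .font_rows[[variant]][[as.character(digit)]]
  do.call(rbind, lapply(rows, function(r) as.integer(strsplit(r, "")[[1]])))
}

#' Render a digit glyph
#'
#' Draws a digit from the built-in dot-matrix font at the requested height,
#' with optional rotation, scale jitter and additive noise. Output is a
#' grayscale ink matrix (1 = full ink).
#'
#' @param digit integer 0-9.
#' @param height glyph height in px.
#' @param rotation_deg rotation applied to the glyph.
#' @param variant font variant, `"a"` or `"b"`.
#' @param noise_sd additive Gaussian pixel noise SD.
#' @param widen horizontal scale factor (1 = nominal aspect).
#' @return numeric matrix in `[0, 1]`, ink as high values.
#' @export
render_digit <- function(digit, height = 32L, rotation_deg = 0, variant = "a",
                         noise_sd = 0, widen = 1) {
  bm <- digit_bitmap(digit, variant)
  h <- as.integer(height)
  w <- max(4L, as.integer(round(height * 5 / 7 * widen)))
  # upscale by bilinear sampling of the bitmap grid
  ys <- seq(0.5 + 1e-6, nrow(bm) + 0.5 - 1e-6, length.out = h)
  xs <- seq(0.5 + 1e-6, ncol(bm) + 0.5 - 1e-6, length.out = w)
  g <- matrix(bilinear_sample(bm + 0, rep(pmin(pmax(xs, 1), ncol(bm)), each = h),
                              rep(pmin(pmax(ys, 1), nrow(bm)), times = w),
                              fill = 0), h, w)
  g <- (g > 0.45) + 0
  if (rotation_deg != 0) {
    th <- rotation_deg * pi / 180
    cy <- (h + 1) / 2; cx <- (w + 1) / 2
    gx <- rep(seq_len(w), each = h); gy <- rep(seq_len(h), times = w)
    sx <- cx + cos(th) * (gx - cx) - sin(th) * (gy - cy)
    sy <- cy + sin(th) * (gx - cx) + cos(th) * (gy - cy)
    g <- matrix(bilinear_sample(g, sx, sy, fill = 0), h, w)
  }
  if (noise_sd > 0) g <- clamp01(g + stats::rnorm(length(g), 0, noise_sd))
  g
}

#' Normalize a glyph to the classifier input frame
#'
#' Crops to the ink bounding box, rescales the longer side to 20 px, and
#' centers the glyph by center of mass in a 28 x 28 frame -- the standard
#' handwritten-digit preprocessing.
#'
#' @param glyph numeric or logical ink matrix (ink = high/`TRUE`).
#' @param size output frame side (default 28).
#' @return `size x size` numeric matrix in `[0, 1]`.
#' @export
normalize_glyph <- function(glyph, size = 28L) {
  g <- glyph + 0
  if (max(g) <= 0) iop_error("ClassificationError", "normalize_glyph: blank glyph")
  g <- g / max(g)
  rows <- which(rowSums(g) > 0.05); cols <- which(colSums(g) > 0.05)
  g <- g[min(rows):max(rows), min(cols):max(cols), drop = FALSE]
  h <- nrow(g); w <- ncol(g)
  s <- 20 / max(h, w)
  nh <- max(1L, round(h * s)); nw <- max(1L, round(w * s))
  ys <- seq(1, h, length.out = nh); xs <- seq(1, w, length.out = nw)
  small <- matrix(bilinear_sample(g, rep(xs, each = nh), rep(ys, times = nw),
                                  fill = 0), nh, nw)
  out <- matrix(0, size, size)
  # center of mass placement
  tot <- sum(small)
  cy <- sum(row(small) * small) / tot; cx <- sum(col(small) * small) / tot
  y0 <- round(size / 2 - cy); x0 <- round(size / 2 - cx)
  yy <- seq_len(nh) + y0; xx <- seq_len(nw) + x0
  ok_y <- yy >= 1 & yy <= size; ok_x <- xx >= 1 & xx <= size
  out[yy[ok_y], xx[ok_x]] <- small[ok_y, ok_x, drop = FALSE]
  out
}
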