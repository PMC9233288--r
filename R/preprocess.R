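# Preprocessing: binarize the scan, find the chart's main frame as the
# largest contour reduced to a quadrilateral, and warp the frame interior to
# the canonical raster so later stages can use fixed pixel positions.

# 1-D Gaussian kernel for a given odd window; sigma follows the common
# ksize-derived convention sigma = 0.3 * ((ksize - 1) / 2 - 1) + 0.8.
gaussian_kernel1d <- function(window) {
  r <- (window - 1L) / 2L
  sigma <- 0.3 * ((window - 1) * 0.5 - 1) + 0.8
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

#' Adaptive Gaussian binarization
#'
#' Thresholds each pixel against the Gaussian-weighted mean of its
#' `window x window` neighborhood minus a constant offset: a pixel is
#' foreground (ink) iff its intensity is strictly below the local mean minus
#' `offset` gray levels (8-bit scale). The border is handled by edge
#' replication. Defaults are a 27 x 27 window with offset 10.
#'
#' @param image grayscale matrix in `[0, 1]` (or 8-bit `0..255`).
#' @param window odd neighborhood size, >= 3.
#' @param offset constant subtracted from the local mean, in 8-bit gray levels.
#' @return logical matrix, `TRUE` = foreground ink.
#' @export
binarize_adaptive <- function(image, window = 27L, offset = 10) {
  if (!is.matrix(image) || length(image) == 0L)
    iop_error("InputError", "binarize_adaptive: image must be a non-empty matrix")
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    iop_error("InputError", "binarize_adaptive: window must be odd and >= 3")
  if (max(image) > 1) image <- image / 255
  m <- gaussian_blur(image, window)
  image < m - offset / 255
}

# Separable Gaussian smoothing with replicate borders.
gaussian_blur <- function(image, window) {
  k <- gaussian_kernel1d(window)
  r <- (window - 1L) / 2L
  h <- nrow(image); w <- ncol(image)
  pad_r <- image[c(rep(1L, r), seq_len(h), rep(h, r)), , drop = FALSE]
  tmp <- matrix(0, h, w)
  for (j in seq_len(window))
    tmp <- tmp + k[j] * pad_r[(seq_len(h)) + (j - 1L), , drop = FALSE]
  pad_c <- tmp[, c(rep(1L, r), seq_len(w), rep(w, r)), drop = FALSE]
  out <- matrix(0, h, w)
  for (j in seq_len(window))
    out <- out + k[j] * pad_c[, (seq_len(w)) + (j - 1L), drop = FALSE]
  out
}

# Shoelace area of a polygon given as an n x 2 matrix of (x, y).
polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Douglas-Peucker simplification of an open polyline (n x 2 matrix).
dp_open <- function(pts, eps) {
  n <- nrow(pts)
  if (n <= 2L) return(pts)
  a <- pts[1, ]; b <- pts[n, ]
  ab <- b - a
  len <- sqrt(sum(ab^2))
  d <- if (len < 1e-9) {
    sqrt((pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2)
  } else {
    abs(ab[1] * (a[2] - pts[, 2]) - ab[2] * (a[1] - pts[, 1])) / len
  }
  i <- which.max(d)
  if (d[i] <= eps) return(pts[c(1L, n), , drop = FALSE])
  left <- dp_open(pts[1:i, , drop = FALSE], eps)
  right <- dp_open(pts[i:n, , drop = FALSE], eps)
  rbind(left[-nrow(left), , drop = FALSE], right)
}

# Douglas-Peucker for a closed polygon: split at the two mutually farthest
# vertices, simplify each chain, and rejoin.
dp_closed <- function(pts, eps) {
  n <- nrow(pts)
  if (n <= 4L) return(pts)
  d2 <- as.matrix(stats::dist(pts))
  idx <- which(d2 == max(d2), arr.ind = TRUE)[1, ]
  i <- min(idx); j <- max(idx)
  chain1 <- pts[i:j, , drop = FALSE]
  chain2 <- pts[c(j:n, 1:i), , drop = FALSE]
  s1 <- dp_open(chain1, eps)
  s2 <- dp_open(chain2, eps)
  out <- rbind(s1[-nrow(s1), , drop = FALSE], s2[-nrow(s2), , drop = FALSE])
  unique(out)
}

# Intersection of two infinite lines, each given as (point, direction).
line_intersect <- function(p1, d1, p2, d2) {
  A <- cbind(d1, -d2)
  if (abs(det(A)) < 1e-9) return(c(NA_real_, NA_real_))
  t <- solve(A, p2 - p1)
  p1 + t[1] * d1
}

# Total-least-squares line through points: returns list(point, direction).
fit_line_tls <- function(pts) {
  ctr <- colMeans(pts)
  v <- prcomp(pts, center = TRUE, scale. = FALSE)$rotation[, 1]
  list(p = ctr, d = v)
}

#' Locate the chart's main frame in a binarized scan
#'
#' Selects the largest connected contour (by convex-hull area), simplifies its
#' hull with the Douglas-Peucker algorithm -- doubling the tolerance from 1%
#' of the hull perimeter until at most four vertices remain -- and refines the
#' four corners by total-least-squares line fits to the hull-boundary pixels
#' of each side, intersecting adjacent side lines. The line-fit refinement is
#' what recovers true corners when part of the frame is cut off. The
#' quadrilateral must be close to a rectangle: every interior angle within
#' `angle_tol_deg` of 90 degrees.
#'
#' @param binary logical foreground matrix from [binarize_adaptive()].
#' @param angle_tol_deg rectangle angle tolerance (default 10 degrees).
#' @param min_frame_fraction smallest acceptable frame area as a fraction of
#'   the scan area (default 0.2).
#' @return a 4 x 2 matrix of corners `(x, y)`, ordered clockwise from
#'   top-left, of class `quadrilateral`.
#' @export
find_main_frame <- function(binary, angle_tol_deg = 10, min_frame_fraction = 0.2) {
  if (!is.matrix(binary) || length(binary) == 0L)
    iop_error("InputError", "find_main_frame: binary must be a non-empty matrix")
  h <- nrow(binary); w <- ncol(binary)
  lab <- label_components(binary)
  counts <- tabulate(lab[lab > 0L])
  if (length(counts) == 0L)
    iop_error("FrameNotFound", "find_main_frame: no foreground components")
  cand <- order(counts, decreasing = TRUE)
  cand <- cand[seq_len(min(5L, sum(counts > 0)))]
  best <- NULL; best_area <- -1
  for (id in cand) {
    ij <- which(lab == id, arr.ind = TRUE)
    pts <- cbind(x = ij[, 2], y = ij[, 1])
    hull <- pts[grDevices::chull(pts), , drop = FALSE]
    if (nrow(hull) < 3L) next
    a <- polygon_area(hull)
    if (a > best_area) { best_area <- a; best <- list(pts = pts, hull = hull) }
  }
  if (is.null(best) || best_area < min_frame_fraction * h * w)
    iop_error("FrameNotFound", sprintf(
      "find_main_frame: largest contour covers %.1f%% of the scan (need >= %.0f%%)",
      100 * max(best_area, 0) / (h * w), 100 * min_frame_fraction))

  hull <- best$hull
  perim <- sum(sqrt(rowSums((hull - hull[c(2:nrow(hull), 1), ])^2)))
  eps <- 0.01 * perim
  approx <- dp_closed(hull, eps)
  while (nrow(approx) > 4L) {
    eps <- eps * 2
    approx <- dp_closed(hull, eps)
  }
  if (nrow(approx) < 4L)
    iop_error("FrameNotRectangular",
              "find_main_frame: contour degenerates below four vertices")
  corners <- order_corners(approx)

  # Hull-boundary pixels: component pixels within 2.5 px of the hull polygon.
  # Iterated side fits: each pass re-selects inliers around the current side
  # lines, so corners converge onto the true edges even when a Douglas-Peucker
  # vertex sits on a cut-off chord.
  near <- hull_boundary_pixels(best$pts, hull, tol = 2.5)
  for (tol_fit in c(6, 4, 3, 2, 2)) {
    refined <- refine_corners(corners, near, tol_fit)
    if (!is.null(refined)) corners <- refined
  }
  corners <- order_corners(corners)

  ang <- quad_angles(corners)
  if (any(abs(ang - 90) > angle_tol_deg))
    iop_error("FrameNotRectangular", sprintf(
      "find_main_frame: interior angles (%s) outside 90 +/- %g degrees",
      paste(round(ang, 1), collapse = ", "), angle_tol_deg))
  structure(corners, class = c("quadrilateral", class(corners)),
            angles = ang)
}

# Pixels lying within tol of the convex hull outline.
hull_boundary_pixels <- function(pts, hull, tol = 2.5) {
  m <- nrow(hull)
  dmin <- rep(Inf, nrow(pts))
  for (i in seq_len(m)) {
    a <- hull[i, ]; b <- hull[if (i == m) 1L else i + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 < 1e-9) next
    t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
    t <- pmin(pmax(t, 0), 1)
    dx <- pts[, 1] - (a[1] + t * ab[1])
    dy <- pts[, 2] - (a[2] + t * ab[2])
    dmin <- pmin(dmin, dx * dx + dy * dy)
  }
  pts[dmin <= tol^2, , drop = FALSE]
}

# Re-estimate corners by fitting a TLS line to the pixels of each side
# (excluding the corner neighborhoods) and intersecting adjacent sides.
refine_corners <- function(corners, near, tol_fit) {
  lines <- vector("list", 4L)
  for (i in 1:4) {
    a <- corners[i, ]; b <- corners[if (i == 4) 1L else i + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 < 1e-9) return(NULL)
    t <- ((near[, 1] - a[1]) * ab[1] + (near[, 2] - a[2]) * ab[2]) / len2
    d <- abs(ab[1] * (a[2] - near[, 2]) - ab[2] * (a[1] - near[, 1])) / sqrt(len2)
    sel <- t >= 0.04 & t <= 0.96 & d <= tol_fit
    if (sum(sel) < 10L) return(NULL)
    lines[[i]] <- fit_line_tls(near[sel, , drop = FALSE])
  }
  out <- matrix(0, 4L, 2L, dimnames = list(NULL, c("x", "y")))
  for (i in 1:4) {
    prev <- if (i == 1) 4L else i - 1L
    p <- line_intersect(lines[[prev]]$p, lines[[prev]]$d,
                        lines[[i]]$p, lines[[i]]$d)
    if (anyNA(p)) return(NULL)
    out[i, ] <- p
  }
  out
}

# Order 4 corners clockwise (screen sense, y down) starting at top-left.
order_corners <- function(p) {
  ctr <- colMeans(p)
  ord <- order(atan2(p[, 2] - ctr[2], p[, 1] - ctr[1]))
  p <- p[ord, , drop = FALSE]
  start <- which.min(p[, 1] + p[, 2])
  p <- p[((seq_len(4L) + start - 2L) %% 4L) + 1L, , drop = FALSE]
  colnames(p) <- c("x", "y")
  p
}

# Interior angles (degrees) of an ordered quadrilateral.
quad_angles <- function(p) {
  vapply(1:4, function(i) {
    a <- p[if (i == 1) 4L else i - 1L, ]
    b <- p[i, ]
    c <- p[if (i == 4) 1L else i + 1L, ]
    u <- a - b; v <- c - b
    acos(pmin(pmax(sum(u * v) / sqrt(sum(u^2) * sum(v^2)), -1), 1)) * 180 / pi
  }, numeric(1))
}

# Homography (3x3) mapping (x, y) in `from` to (x, y) in `to`; both 4 x 2.
homography_from_points <- function(from, to) {
  A <- matrix(0, 8, 8); b <- numeric(8)
  for (i in 1:4) {
    x <- from[i, 1]; y <- from[i, 2]
    u <- to[i, 1]; v <- to[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    A[2 * i, ]     <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    b[2 * i - 1] <- u; b[2 * i] <- v
  }
  h <- solve(A, b)
  matrix(c(h, 1), 3, 3, byrow = TRUE)
}

# Apply a homography to an n x 2 point matrix.
apply_homography <- function(H, pts) {
  q <- cbind(pts, 1) %*% t(H)
  q[, 1:2] / q[, 3]
}

# Bilinear sampling of an image (matrix or h x w x 3) at fractional
# coordinates; out-of-range samples return `fill`.
bilinear_sample <- function(px, xs, ys, fill = 1) {
  d <- dim(px)
  h <- d[1]; w <- d[2]
  inside <- xs >= 1 & xs <= w & ys >= 1 & ys <= h
  # clamp indices so arithmetic stays legal; overwritten with fill later
  x0c <- pmin(pmax(floor(xs), 1), w - 1); y0c <- pmin(pmax(floor(ys), 1), h - 1)
  fx <- xs - x0c; fy <- ys - y0c
  i00 <- (x0c - 1) * h + y0c
  sample_plane <- function(pl) {
    v <- (1 - fx) * ((1 - fy) * pl[i00] + fy * pl[i00 + 1]) +
      fx * ((1 - fy) * pl[i00 + h] + fy * pl[i00 + h + 1])
    v[!inside] <- fill
    v
  }
  if (length(d) == 2L) return(sample_plane(px))
  out <- vapply(seq_len(d[3]), function(ch) sample_plane(px[, , ch]),
                numeric(length(xs)))
  out
}

#' Warp the frame interior onto the canonical raster
#'
#' Perspective-maps the quadrilateral onto the template's canonical
#' rectangle, so that every scan -- regardless of resolution, rotation or
#' mild skew -- yields a raster of identical size on which template pixel
#' positions are valid.
#'
#' @param scan a [raw_scan()] (or RGB array).
#' @param frame quadrilateral from [find_main_frame()].
#' @param template a [chart_template()].
#' @param min_frame_fraction reject frames smaller than this fraction of the
#'   scan area.
#' @return object of class `canonical_chart` with fields `pixels`,
#'   `transform` (canonical-to-source homography) and `template`.
#' @export
crop_to_canonical <- function(scan, frame, template = chart_template(),
                              min_frame_fraction = 0.2) {
  px <- ensure_rgb(chart_pixels(scan))
  d <- dim(px)
  if (polygon_area(frame) < min_frame_fraction * d[1] * d[2])
    iop_error("FrameNotFound", "crop_to_canonical: degenerate frame quadrilateral")
  W <- unname(template$canonical_size["width"])
  H <- unname(template$canonical_size["height"])
  dst <- cbind(x = c(1, W, W, 1), y = c(1, 1, H, H))
  Hm <- homography_from_points(dst, unclass(frame)[, 1:2])
  grid_x <- rep(seq_len(W), each = H)
  grid_y <- rep(seq_len(H), times = W)
  src <- apply_homography(Hm, cbind(grid_x, grid_y))
  out <- bilinear_sample(px, src[, 1], src[, 2], fill = 1)
  dim(out) <- c(H, W, 3L)
  structure(list(pixels = out, transform = Hm, template = template,
                 source_id = if (inherits(scan, "raw_scan")) scan$source_id else "array"),
            class = "canonical_chart")
}

#' @export
print.canonical_chart <- function(x, ...) {
  d <- dim(x$pixels)
  cat("<canonical_chart> ", x$source_id, ": ", d[2], " x ", d[1], " px\n", sep = "")
  invisible(x)
}

#' Run binarization, frame detection and cropping on one scan
#'
#' Convenience wrapper chaining [to_gray()], [binarize_adaptive()],
#' [find_main_frame()] and [crop_to_canonical()].
#'
#' @param scan a [raw_scan()].
#' @param template a [chart_template()].
#' @param window,offset see [binarize_adaptive()].
#' @param angle_tol_deg,min_frame_fraction see [find_main_frame()].
#' @return a `canonical_chart`.
#' @export
preprocess_scan <- function(scan, template = chart_template(),
                            window = 27L, offset = 10,
                            angle_tol_deg = 10, min_frame_fraction = 0.2) {
  bin <- binarize_adaptive(to_gray(scan), window = window, offset = offset)
  frame <- find_main_frame(bin, angle_tol_deg = angle_tol_deg,
                           min_frame_fraction = min_frame_fraction)
  crop_to_canonical(scan, frame, template, min_frame_fraction = min_frame_fraction)
}
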