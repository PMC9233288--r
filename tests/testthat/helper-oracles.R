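# Shared fixtures and independent oracles. Oracles are deliberately written
# as naive loops so they share no code path with the package internals.

tpl_test <- chart_template()

# Brute-force adaptive Gaussian threshold: per-pixel weighted mean over a
# replicated-border window, computed with explicit loops.
oracle_binarize <- function(image, window, offset) {
  if (max(image) > 1) image <- image / 255
  r <- (window - 1) / 2
  sigma <- 0.3 * ((window - 1) * 0.5 - 1) + 0.8
  k1 <- exp(-((-r:r)^2) / (2 * sigma^2)); k1 <- k1 / sum(k1)
  k2 <- outer(k1, k1)
  h <- nrow(image); w <- ncol(image)
  out <- matrix(FALSE, h, w)
  for (y in seq_len(h)) for (x in seq_len(w)) {
    acc <- 0
    for (dy in -r:r) for (dx in -r:r) {
      yy <- min(max(y + dy, 1), h); xx <- min(max(x + dx, 1), w)
      acc <- acc + k2[dy + r + 1, dx + r + 1] * image[yy, xx]
    }
    out[y, x] <- image[y, x] < acc - offset / 255
  }
  out
}

# Exhaustive assignment oracle: over all injective detection->truth maps that
# respect the (eye, day, clock) key, find the minimum total |value difference|
# assignment; returns matched count, total distance, FP and FN counts.
oracle_match <- function(detected, truth) {
  if (inherits(truth, "ground_truth")) truth <- truth$entries
  key <- function(d, i) paste(d$eye[i], d$day[i], d$clock[i])
  nd <- nrow(detected); nt <- nrow(truth)
  best <- list(n = -1, dist = Inf)
  # recursive enumeration over truth entries
  rec <- function(ti, used, nmatch, dist) {
    if (ti > nt) {
      if (nmatch > best$n || (nmatch == best$n && dist < best$dist))
        best <<- list(n = nmatch, dist = dist)
      return(invisible())
    }
    # option: truth ti unmatched
    rec(ti + 1, used, nmatch, dist)
    for (j in seq_len(nd)) {
      if (!used[j] && key(detected, j) == key(truth, ti)) {
        u <- used; u[j] <- TRUE
        rec(ti + 1, u, nmatch + 1,
            dist + abs(detected$value_mmhg[j] - truth$value_mmhg[ti]))
      }
    }
  }
  rec(1, rep(FALSE, max(nd, 1)), 0, 0)
  list(matched = best$n, distance = best$dist,
       fp = nd - best$n, fn = nt - best$n)
}

# A clean rendered single-day chart plus its canonical crop.
make_clean_chart <- function(values_od = c(15, 18, 17, 14, 16),
                             values_os = NULL, seed = 1, ...) {
  tr <- ground_truth(values_od = values_od, values_os = values_os,
                     template = tpl_test)
  scan <- render_chart(tr, render_config(seed = seed, ...), tpl_test)
  list(scan = scan, truth = attr(scan, "truth"),
       chart = preprocess_scan(scan, tpl_test))
}

# Header-only canonical chart with a stamped date, for fast metadata
# round-trip tests (no full form rendering).
make_date_chart <- function(date, seed = 1, tpl = tpl_test) {
  set.seed(seed)
  W <- unname(tpl$canonical_size["width"]); H <- unname(tpl$canonical_size["height"])
  px <- array(1, c(H, W, 3))
  dr <- tpl$date_region
  gh <- round((dr[4] - dr[2]) * 0.72)
  xpen <- dr[1] + 14
  ybase <- dr[2] + round((dr[4] - dr[2] - gh) / 2)
  stamp <- function(px, g, x0, y0) {
    ij <- which(g > 0.35, arr.ind = TRUE)
    for (ch in 1:3) px[cbind(y0 + ij[, 1] - 1L, x0 + ij[, 2] - 1L, ch)] <- 0.15
    px
  }
  for (chr in strsplit(format(date, "%d.%m.%Y"), "")[[1]]) {
    if (chr == ".") {
      px[(ybase + gh - 4):(ybase + gh - 1), (xpen):(xpen + 3), ] <- 0.15
      xpen <- xpen + 10
    } else {
      g <- render_digit(as.integer(chr), height = gh,
                        rotation_deg = stats::runif(1, -6, 6),
                        variant = sample(c("a", "b"), 1),
                        widen = stats::runif(1, 0.9, 1.1))
      px <- stamp(px, g, xpen, ybase)
      xpen <- xpen + ncol(g) + 6
    }
  }
  structure(list(pixels = px, template = tpl, source_id = "header-fixture"),
            class = "canonical_chart")
}

# Fake digit/delimiter region list for direct parse_date tests.
fake_regions <- function(roles) {
  lapply(roles, function(r) list(role = r, warning = ""))
}
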