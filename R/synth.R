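# Synthetic chart renderer and cohort simulator. The renderer emulates the
# standard German 24-hour IOP form (frame, uneven time gridlines, compressed
# pressure axis, printed name label, handwritten date, blue/red marks joined
# by polylines, scan noise, rotation, corner cut-off) and records ground
# truth, so extraction accuracy is measurable without any patient scans.

# ---- low-level drawing ------------------------------------------------------
# Drawing helpers return linear pixel indices into an h x w plane; painting
# happens in bulk on per-channel planes held in an environment, so the large
# canvas is mutated in place instead of being copied per stroke.

px_clip <- function(h, w, xs, ys) {
  keep <- xs >= 1 & xs <= w & ys >= 1 & ys <= h
  (xs[keep] - 1L) * h + ys[keep]
}

px_line <- function(h, w, x1, y1, x2, y2, width = 1) {
  len <- max(abs(x2 - x1), abs(y2 - y1), 1)
  t <- seq(0, 1, length.out = ceiling(len * 2) + 1)
  xs <- round(x1 + t * (x2 - x1)); ys <- round(y1 + t * (y2 - y1))
  r <- floor((width - 1) / 2); r2 <- ceiling((width - 1) / 2)
  off <- expand.grid(dx = -r:r2, dy = -r:r2)
  px_clip(h, w,
          rep(xs, nrow(off)) + rep(off$dx, each = length(xs)),
          rep(ys, nrow(off)) + rep(off$dy, each = length(ys)))
}

px_disc <- function(h, w, cx, cy, radius = 4) {
  off <- expand.grid(dx = -radius:radius, dy = -radius:radius)
  off <- off[off$dx^2 + off$dy^2 <= radius^2 + 0.5, ]
  px_clip(h, w, round(cx) + off$dx, round(cy) + off$dy)
}

px_rect <- function(h, w, x1, y1, x2, y2) {
  px_clip(h, w, rep(x1:x2, each = y2 - y1 + 1L), rep(y1:y2, times = x2 - x1 + 1L))
}

px_glyph <- function(h, w, glyph, x0, y0) {
  ij <- which(glyph > 0.35, arr.ind = TRUE)
  if (nrow(ij) == 0L) return(integer(0))
  px_clip(h, w, x0 + ij[, 2] - 1L, y0 + ij[, 1] - 1L)
}

# ---- configuration and ground truth ----------------------------------------

#' Renderer configuration
#'
#' All stochastic rendering choices (jitter, rotation draw, noise, glyph
#' perturbations) are driven by `seed`, so a given config renders
#' byte-identically every time.
#'
#' @param seed integer seed; fully determines the rendered image.
#' @param noise_sigma additive Gaussian intensity noise SD, 8-bit gray levels.
#' @param rotation_deg page rotation: a scalar, or a `c(min, max)` range to
#'   draw from.
#' @param jitter_px maximum mark placement jitter (uniform, both axes).
#' @param marker mark style: `"dot"`, `"cross"` or `"tick"`.
#' @param join_lines draw the clinician's connecting polyline between marks.
#' @param cutoff_fraction fraction (0-0.2) of the frame's top-right corner cut
#'   off, emulating a mis-fed scan.
#' @param days number of charted days (1-6).
#' @return object of class `render_config`.
#' @export
render_config <- function(seed = 1L, noise_sigma = 0, rotation_deg = 0,
                          jitter_px = 0, marker = c("dot", "cross", "tick"),
                          join_lines = FALSE, cutoff_fraction = 0, days = 1L) {
  marker <- match.arg(marker)
  if (cutoff_fraction < 0 || cutoff_fraction > 0.2)
    iop_error("InputError", "render_config: cutoff_fraction must be in [0, 0.2]")
  if (!all(is.finite(c(noise_sigma, rotation_deg, jitter_px))))
    iop_error("InputError", "render_config: ranges must be finite")
  structure(list(seed = as.integer(seed), noise_sigma = noise_sigma,
                 rotation_deg = rotation_deg, jitter_px = jitter_px,
                 marker = marker, join_lines = isTRUE(join_lines),
                 cutoff_fraction = cutoff_fraction, days = as.integer(days)),
            class = "render_config")
}

#' Ground truth for one synthetic chart
#'
#' Holds the truly plotted entries per eye plus the header content. The
#' renderer augments `entries` with the drawn pixel positions (canonical
#' coordinates), which evaluation uses as provenance.
#'
#' @param values_od,values_os numeric vectors of IOP values (mmHg), one per
#'   slot per day, in slot order; `NULL` for an eye with no curve.
#' @param days number of charted days.
#' @param exam_date a `Date`.
#' @param patient_name machine-label text, `"Surname, Givenname"`.
#' @param patient_id identifier used in truth tables.
#' @param template a [chart_template()].
#' @return object of class `ground_truth`.
#' @export
ground_truth <- function(values_od = NULL, values_os = NULL, days = 1L,
                         exam_date = as.Date("2018-03-12"),
                         patient_name = "Mustermann, Erika",
                         patient_id = "P001",
                         template = chart_template()) {
  days <- as.integer(days)
  slots <- template_slot_x(template, days)
  mk <- function(v, eye) {
    if (is.null(v)) return(NULL)
    if (length(v) != nrow(slots))
      iop_error("InputError", sprintf(
        "ground_truth: %s needs %d values for %d day(s)", eye, nrow(slots), days))
    data.frame(eye = eye, day = slots$day, clock = slots$clock,
               value_mmhg = as.numeric(v))
  }
  entries <- rbind(mk(values_od, "OD"), mk(values_os, "OS"))
  if (is.null(entries) || nrow(entries) == 0L)
    iop_error("InputError", "ground_truth: at least one eye needs values")
  rng <- template$y_axis$mmhg
  if (any(entries$value_mmhg < rng[1] | entries$value_mmhg > rng[3]))
    iop_error("RangeError", "ground_truth: values outside the chartable axis range")
  structure(list(patient_id = patient_id, patient_name = patient_name,
                 exam_date = exam_date, days = days, entries = entries),
            class = "ground_truth")
}

eye_color <- function(eye) {
  if (eye == "OD") c(0.10, 0.16, 0.72) else c(0.80, 0.10, 0.12)
}

# ---- the renderer -----------------------------------------------------------

#' Render a synthetic chart scan
#'
#' Draws the form (frame, gridlines, header with printed name label and
#' handwritten-style date), plots the ground-truth entries in blue (right
#' eye) and red (left eye), then applies the configured corner cut-off,
#' rotation and scan noise. The drawn mark centers (canonical coordinates,
#' before rotation) are recorded back onto the returned scan's
#' `attr(, "truth")`.
#'
#' @param truth a [ground_truth()].
#' @param config a [render_config()].
#' @param template a [chart_template()].
#' @return a [raw_scan()] with attribute `truth`.
#' @export
render_chart <- function(truth, config = render_config(), template = chart_template()) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  W <- unname(template$canonical_size["width"])
  H <- unname(template$canonical_size["height"])
  m <- 60L
  ph <- H + 2L * m; pw <- W + 2L * m
  cv <- new.env(parent = emptyenv())
  cv$r <- matrix(1, ph, pw); cv$g <- matrix(1, ph, pw); cv$b <- matrix(1, ph, pw)
  paint <- function(idx, col) {
    cv$r[idx] <- col[1]; cv$g[idx] <- col[2]; cv$b[idx] <- col[3]
  }
  cx <- function(x) x + m; cy <- function(y) y + m   # canonical -> page

  # frame: strokes centered on the canonical rectangle edges
  fcol <- c(0.05, 0.05, 0.05)
  paint(c(px_line(ph, pw, cx(1), cy(1), cx(W), cy(1), 3),
          px_line(ph, pw, cx(W), cy(1), cx(W), cy(H), 3),
          px_line(ph, pw, cx(W), cy(H), cx(1), cy(H), 3),
          px_line(ph, pw, cx(1), cy(H), cx(1), cy(1), 3)), fcol)

  ax <- template$y_axis
  y_top <- ax$y_px[3]; y_bot <- ax$y_px[1]
  xs_plot <- range(template$time_slots$x)

  # horizontal pressure gridlines (light), every 10 mmHg
  for (v in seq(0, ax$mmhg[3], by = 10)) {
    yv <- value_to_pixel(v, template)
    paint(px_line(ph, pw, cx(xs_plot[1] - 30), cy(yv), cx(xs_plot[2] + 10), cy(yv), 1),
          c(0.72, 0.72, 0.72))
  }
  # vertical time gridlines for the charted days (darker; these are the lines
  # the Hough step must find)
  slots <- template_slot_x(template, config$days)
  for (x in slots$x)
    paint(px_line(ph, pw, cx(x), cy(y_top), cx(x), cy(y_bot), 2), c(0.35, 0.35, 0.35))

  # header: printed-name mock label (gray sticker with dark text bars)
  hr <- template$header_region
  paint(px_rect(ph, pw, cx(hr[1]), cy(hr[2]), cx(hr[3]), cy(hr[4])),
        c(0.88, 0.88, 0.88))
  bar_y <- round(seq(hr[2] + 12, hr[4] - 10, length.out = 2))
  for (by in bar_y) {
    xb <- hr[1] + 10
    while (xb < hr[3] - 30) {
      wbar <- sample(15:40, 1)
      paint(px_rect(ph, pw, cx(xb), cy(by), cx(min(xb + wbar, hr[3] - 10)), cy(by + 8)),
            c(0.2, 0.2, 0.22))
      xb <- xb + wbar + sample(6:14, 1)
    }
  }

  # handwritten-style date in the date region
  dr <- template$date_region
  date_str <- format(truth$exam_date, "%d.%m.%Y")
  gh <- round((dr[4] - dr[2]) * 0.72)
  xpen <- dr[1] + 14
  ybase <- dr[2] + round((dr[4] - dr[2] - gh) / 2)
  ink <- c(0.15, 0.15, 0.19)   # blue-black pen: dark, low chroma
  for (chr in strsplit(date_str, "")[[1]]) {
    if (chr == ".") {
      paint(px_disc(ph, pw, cx(xpen + 2), cy(ybase + gh - 3), 2), ink)
      xpen <- xpen + 10
    } else {
      g <- render_digit(as.integer(chr), height = gh,
                        rotation_deg = stats::runif(1, -6, 6),
                        variant = sample(c("a", "b"), 1),
                        widen = stats::runif(1, 0.9, 1.1))
      paint(px_glyph(ph, pw, g, cx(xpen), cy(ybase + round(stats::runif(1, -2, 2)))), ink)
      xpen <- xpen + ncol(g) + 6
    }
  }

  # marks (and the connecting polyline clinicians draw)
  ent <- truth$entries
  ent$x_px <- NA_real_; ent$y_px <- NA_real_
  slot_x <- stats::setNames(slots$x, paste(slots$day, slots$clock))
  for (eye in unique(ent$eye)) {
    idx <- which(ent$eye == eye)
    col <- clamp01(eye_color(eye) + stats::rnorm(3, 0, 0.02))
    for (i in idx) {
      x0 <- slot_x[paste(ent$day[i], ent$clock[i])]
      y0 <- value_to_pixel(ent$value_mmhg[i], template)
      jx <- if (config$jitter_px > 0) stats::runif(1, -config$jitter_px, config$jitter_px) else 0
      jy <- if (config$jitter_px > 0) stats::runif(1, -config$jitter_px, config$jitter_px) else 0
      ent$x_px[i] <- round(x0 + jx); ent$y_px[i] <- round(y0 + jy)
    }
    if (config$join_lines && length(idx) > 1L) {
      for (k in seq_len(length(idx) - 1L)) {
        i <- idx[k]; j <- idx[k + 1L]
        paint(px_line(ph, pw, cx(ent$x_px[i]), cy(ent$y_px[i]),
                      cx(ent$x_px[j]), cy(ent$y_px[j]), 2), col)
      }
    }
    for (i in idx) {
      px <- cx(ent$x_px[i]); py <- cy(ent$y_px[i])
      paint(switch(config$marker,
        dot = px_disc(ph, pw, px, py, 4),
        cross = c(px_line(ph, pw, px - 5, py - 5, px + 5, py + 5, 2),
                  px_line(ph, pw, px - 5, py + 5, px + 5, py - 5, 2)),
        tick = px_line(ph, pw, px - 6, py, px + 6, py, 3)), col)
    }
  }
  truth$entries <- ent

  # corner cut-off: white out a triangle over the frame's top-right corner
  if (config$cutoff_fraction > 0) {
    legx <- config$cutoff_fraction * W; legy <- config$cutoff_fraction * H
    xr <- cx(W) + 4; yt <- cy(1) - 4
    gx <- rep(seq_len(pw), each = ph)
    gy <- rep(seq_len(ph), times = pw)
    inside <- (gx - (xr - legx)) / legx + ((yt + legy) - gy) / legy >= 1 &
      gx >= xr - legx & gy <= yt + legy
    paint(which(inside), c(1, 1, 1))
  }

  canvas <- array(c(cv$r, cv$g, cv$b), dim = c(ph, pw, 3L))

  rot <- config$rotation_deg
  if (length(rot) == 2L) rot <- stats::runif(1, rot[1], rot[2])
  if (abs(rot) > 1e-9) canvas <- rotate_image(canvas, rot, fill = 1)

  if (config$noise_sigma > 0) {
    # scanner intensity noise: one luminance draw applied to all channels
    noise <- stats::rnorm(prod(dim(canvas)[1:2]), 0, config$noise_sigma / 255)
    canvas <- clamp01(canvas + rep(noise, 3L))
  }

  scan <- raw_scan(canvas, source_id = paste0("synthetic-", truth$patient_id,
                                              "-seed", config$seed))
  attr(scan, "truth") <- truth
  scan
}

# Rotate an image about its center (degrees, screen clockwise), bilinear.
rotate_image <- function(px, deg, fill = 1) {
  d <- dim(px)
  h <- d[1]; w <- d[2]
  th <- deg * pi / 180
  cxr <- (w + 1) / 2; cyr <- (h + 1) / 2
  gx <- rep(seq_len(w), each = h); gy <- rep(seq_len(h), times = w)
  sx <- cxr + cos(th) * (gx - cxr) - sin(th) * (gy - cyr)
  sy <- cyr + sin(th) * (gx - cxr) + cos(th) * (gy - cyr)
  out <- bilinear_sample(px, sx, sy, fill = fill)
  dim(out) <- d
  out
}

# ---- cohort simulation ------------------------------------------------------

#' Cohort simulation configuration
#'
#' Defaults reproduce the study conditions: mean IOP 15.2 +/- 4.0 mmHg,
#' nycthemeral variation 6.9 +/- 4.2 mmHg, modal acrophase at 10:00 with a
#' spread of 8.4 h, progression prevalence 0.42, and no association between
#' IOP variables and progression (the study found none). Mean arterial
#' pressure defaults (103.9 +/- 12.7 mmHg) are back-derived from the reported
#' ocular perfusion pressure of 59.1 +/- 8.9 mmHg via
#' MOPP = (2/3)(MAP - T_avg).
#'
#' @param n number of patients.
#' @param seed integer seed.
#' @param t_avg_mean,t_avg_sd mean IOP distribution (mmHg).
#' @param iop_var_mean,iop_var_sd nycthemeral variation distribution (mmHg).
#' @param map_mean,map_sd mean arterial pressure distribution (mmHg).
#' @param acrophase_mode modal peak slot (clock string).
#' @param acrophase_modal_mass probability that a patient's peak falls on the
#'   modal slot (default 0.48, the observed share of 10 am acrophases).
#' @param acrophase_spread_h wrapped-normal SD (hours) shaping how the
#'   remaining probability spreads over the other slots.
#' @param prevalence progression prevalence.
#' @param association log-odds of progression per SD of each IOP variable
#'   (0 = null association).
#' @param retry_cap resampling attempts before [simulate_cohort()] fails.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n = 100L, seed = 1L,
                          t_avg_mean = 15.2, t_avg_sd = 4.0,
                          iop_var_mean = 6.9, iop_var_sd = 4.2,
                          map_mean = 103.9, map_sd = 12.7,
                          acrophase_mode = "10:00", acrophase_modal_mass = 0.48,
                          acrophase_spread_h = 8.4,
                          prevalence = 0.42, association = 0,
                          retry_cap = 50L) {
  if (n < 1L) iop_error("InputError", "cohort_config: n must be >= 1")
  if (t_avg_sd < 0 || iop_var_sd < 0 || map_sd < 0)
    iop_error("InputError", "cohort_config: SDs must be >= 0")
  if (prevalence < 0 || prevalence > 1)
    iop_error("InputError", "cohort_config: prevalence must be in [0, 1]")
  structure(as.list(environment()), class = "cohort_config")
}

# truncated-normal draw by rejection
rtrunc_norm <- function(mean, sd, lo, hi, cap = 100L) {
  for (i in seq_len(cap)) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  iop_error("SimulationError", "rtrunc_norm: rejection cap exceeded")
}

# Location parameter of a normal truncated to [lo, hi] whose *mean* equals the
# target; keeps the configured mean meaningful when the bound bites (it does
# for the nycthemeral variation, whose distribution sits close to zero).
trunc_norm_location <- function(target, sd, lo, hi) {
  if (sd == 0) return(target)
  tn_mean <- function(mu) {
    a <- (lo - mu) / sd; b <- (hi - mu) / sd
    z <- stats::pnorm(b) - stats::pnorm(a)
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
  }
  stats::uniroot(function(mu) tn_mean(mu) - target,
                 lower = target - 4 * sd, upper = target + 4 * sd,
                 tol = 1e-8)$root
}

circ_dist_h <- function(a, b) { d <- abs(a - b) %% 24; pmin(d, 24 - d) }

# Probabilities of the peak falling on each slot: the modal slot carries
# `modal_mass`; the rest is spread over the other slots with wrapped-normal
# weights (SD = spread_h) centered on the mode.
acrophase_probs <- function(mode_clock, modal_mass = 0.48, spread_h = 8.4) {
  mode_i <- match(mode_clock, SLOT_TIMES)
  if (is.na(mode_i)) iop_error("InputError", "acrophase_probs: unknown modal slot")
  mu <- SLOT_HOURS[mode_i]
  dens <- vapply(SLOT_HOURS, function(h)
    sum(stats::dnorm(h + 24 * (-2:2), mu, spread_h)), numeric(1))
  p <- numeric(5L)
  p[-mode_i] <- (1 - modal_mass) * dens[-mode_i] / sum(dens[-mode_i])
  p[mode_i] <- modal_mass
  p
}

# Construct 5 slot values with exact range = iop_var and mean ~= t_avg:
# the peak slot takes t_avg + w * iop_var, the circularly opposite trough
# t_avg - (1 - w) * iop_var, and the remaining slots are interpolated along
# circular distance with noise, then recentered to restore the mean.
make_profile_values <- function(t_avg, iop_var, peak_idx, retry_cap = 50L) {
  h <- SLOT_HOURS
  trough_idx <- which.max(circ_dist_h(h, h[peak_idx]))
  mid <- setdiff(1:5, c(peak_idx, trough_idx))
  dfrac <- circ_dist_h(h[mid], h[peak_idx]) / circ_dist_h(h[trough_idx], h[peak_idx])
  # interior slots stay strictly between trough and peak
  dfrac <- 0.15 + 0.7 * dfrac
  build <- function(w, noise_sd) {
    peak_v <- t_avg + w * iop_var
    trough_v <- t_avg - (1 - w) * iop_var
    if (trough_v < 0 || peak_v > 80) return(NULL)
    v <- numeric(5)
    v[peak_idx] <- peak_v; v[trough_idx] <- trough_v
    v[mid] <- peak_v - dfrac * (peak_v - trough_v) +
      if (noise_sd > 0) stats::rnorm(3, 0, noise_sd) else 0
    # recenter the interior values so the realized mean equals t_avg
    v[mid] <- v[mid] + (5 * t_avg - peak_v - trough_v - sum(v[mid])) / 3
    eps <- 0.02 * max(iop_var, 0.5)
    if (!all(v[mid] > trough_v + eps & v[mid] < peak_v - eps)) return(NULL)
    v
  }
  for (attempt in seq_len(retry_cap)) {
    v <- build(stats::runif(1, 0.35, 0.65), iop_var / 8)
    if (!is.null(v)) return(v)
  }
  # deterministic fallback: interpolation without noise, centered split
  for (w in c(0.5, 0.45, 0.55, 0.4, 0.6)) {
    v <- build(w, 0)
    if (!is.null(v)) return(v)
  }
  iop_error("SimulationError",
            "make_profile_values: variation incompatible with mean after retries")
}

#' Simulate a ground-truthed patient cohort
#'
#' Draws per-patient mean IOP and nycthemeral variation from truncated
#' normal distributions, places the daily peak at a slot drawn from the
#' acrophase distribution, constructs 5 slot values consistent with the drawn
#' summary statistics, draws mean arterial pressure, and assigns a
#' progression label by a Bernoulli draw whose logit is linear in the
#' standardized IOP variables times the association strength.
#'
#' @param config a [cohort_config()].
#' @return list with `profiles` (list of `iop_profile`) and `cohort` (one row
#'   per patient: drawn parameters, blood pressure, progression label).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  set.seed(config$seed)
  n <- config$n
  probs <- acrophase_probs(config$acrophase_mode, config$acrophase_modal_mass,
                           config$acrophase_spread_h)
  profiles <- vector("list", n)
  t_avg <- iop_var <- map <- sys_bp <- dia_bp <- numeric(n)
  peak_slot <- character(n)
  mu_a <- trunc_norm_location(config$t_avg_mean, config$t_avg_sd, 1, 80)
  mu_v <- trunc_norm_location(config$iop_var_mean, config$iop_var_sd, 0, 80)
  for (i in seq_len(n)) {
    vals <- NULL
    for (r in seq_len(config$retry_cap)) {
      a <- rtrunc_norm(mu_a, config$t_avg_sd, 1, 80)
      v <- rtrunc_norm(mu_v, config$iop_var_sd, 0, 80)
      if (v > 2 * a || a + v > 80) next
      pk <- sample.int(5L, 1L, prob = probs)
      vals <- tryCatch(make_profile_values(a, v, pk, config$retry_cap),
                       iop_error = function(e) NULL)
      if (!is.null(vals)) break
    }
    if (is.null(vals))
      iop_error("SimulationError", "simulate_cohort: retry cap exceeded")
    t_avg[i] <- a; iop_var[i] <- v; peak_slot[i] <- SLOT_TIMES[pk]
    pp <- rtrunc_norm(45, 8, 20, 80)
    map[i] <- rtrunc_norm(config$map_mean, config$map_sd, 50, 160)
    dia_bp[i] <- map[i] - pp / 3; sys_bp[i] <- dia_bp[i] + pp
    id <- sprintf("SIM%04d", i)
    profiles[[i]] <- iop_profile(
      patient_id = id,
      entries = data.frame(eye = "OD", day = 0L, clock = SLOT_TIMES,
                           value_mmhg = round(vals, 1)))
  }
  realized <- do.call(rbind, lapply(profiles, function(p) {
    s <- summarize_profile(p)
    c(t_max = s$t_max, iop_var = s$iop_var)
  }))
  z1 <- as.numeric(scale(realized[, "t_max"]))
  z2 <- as.numeric(scale(realized[, "iop_var"]))
  if (n == 1L) z1 <- z2 <- 0
  eta <- stats::qlogis(min(max(config$prevalence, 1e-6), 1 - 1e-6)) +
    config$association * z1 + config$association * z2
  prog <- stats::rbinom(n, 1L, stats::plogis(eta))
  list(
    profiles = profiles,
    cohort = data.frame(
      patient_id = vapply(profiles, function(p) p$patient_id, character(1)),
      t_avg_drawn = t_avg, iop_var_drawn = iop_var, peak_slot = peak_slot,
      map = map, systolic = sys_bp, diastolic = dia_bp,
      progressor = prog)
  )
}

#' Write a simulated data set to disk
#'
#' Renders one single-day chart per requested patient and writes `images/`
#' (PNG scans), `truth.csv` (the extraction CSV schema plus true pixel
#' columns) and `cohort.csv` (patient id, blood pressure, progression label).
#'
#' @param sim output of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @param render_config_fn function(seed) returning the [render_config()] for
#'   each chart.
#' @param template a [chart_template()].
#' @param n_images number of charts to render (default all).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, render_config_fn = function(seed)
                               render_config(seed = seed, noise_sigma = 8,
                                             rotation_deg = c(-3, 3),
                                             jitter_px = 2, join_lines = TRUE),
                             template = chart_template(),
                             n_images = length(sim$profiles)) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (i in seq_len(min(n_images, length(sim$profiles)))) {
    p <- sim$profiles[[i]]
    tr <- ground_truth(values_od = p$entries$value_mmhg,
                       patient_id = p$patient_id, template = template)
    scan <- render_chart(tr, render_config_fn(i), template)
    write_image(scan$pixels, file.path(dir, "images", paste0(p$patient_id, ".png")))
    tre <- attr(scan, "truth")$entries
    rows[[i]] <- data.frame(patient_id = p$patient_id,
                            exam_date = as.character(tr$exam_date),
                            eye = tre$eye, day_index = tre$day,
                            clock_time = tre$clock, iop_mmhg = tre$value_mmhg,
                            true_x_px = tre$x_px, true_y_px = tre$y_px)
  }
  utils::write.csv(do.call(rbind, rows), file.path(dir, "truth.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$cohort, file.path(dir, "cohort.csv"), row.names = FALSE)
  invisible(dir)
}
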