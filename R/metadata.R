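# Header metadata: the handwritten examination date (segmented into digit
# glyphs and classified) and the machine-printed patient name (text from a
# pluggable OCR engine, matched with regular expressions).

the <- new.env(parent = emptyenv())   # package-local cache

#' Train the default digit classifier
#'
#' A small softmax neural network (single hidden layer, `nnet`) trained on
#' synthetically rendered digits: both built-in font variants, rotation up to
#' +/- 12 degrees, aspect jitter and pixel noise, normalized to the 28 x 28
#' frame and downsampled to 14 x 14 features. Training is fully seeded and
#' takes seconds, so the package needs no downloaded data set. Any classifier
#' with the same `predict_glyph` contract (28 x 28 input, 10-class
#' probability vector out) can be dropped in instead, e.g. a convolutional
#' network trained on a handwritten-digit corpus.
#'
#' @param seed training seed.
#' @param n_per_class renders per digit class.
#' @param size hidden layer width.
#' @return object of class `digit_classifier` with elements `net` and
#'   `predict_glyph(glyph28)`.
#' @export
train_digit_classifier <- function(seed = 42L, n_per_class = 160L, size = 16L) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  feats <- function(g28) as.vector(downsample2(g28))
  X <- matrix(0, 10L * n_per_class, 196L)
  y <- integer(10L * n_per_class)
  k <- 0L
  for (d in 0:9) for (i in seq_len(n_per_class)) {
    g <- render_digit(d, height = sample(24:40, 1),
                      rotation_deg = stats::runif(1, -12, 12),
                      variant = sample(c("a", "b"), 1),
                      noise_sd = stats::runif(1, 0, 0.12),
                      widen = stats::runif(1, 0.85, 1.15))
    k <- k + 1L
    X[k, ] <- feats(normalize_glyph(g > 0.5))
    y[k] <- d
  }
  Y <- nnet::class.ind(factor(y, levels = 0:9))
  net <- nnet::nnet(X, Y, size = size, softmax = TRUE, maxit = 250,
                    MaxNWts = 50000, decay = 1e-4, trace = FALSE)
  structure(list(
    net = net,
    predict_glyph = function(glyph28) {
      p <- as.numeric(stats::predict(net, matrix(feats(glyph28), 1)))
      names(p) <- as.character(0:9)
      p
    }), class = "digit_classifier")
}

# 2x2 mean-pool a 28x28 matrix to 14x14
downsample2 <- function(g) {
  i <- seq(1, 27, by = 2)
  (g[i, i] + g[i + 1, i] + g[i, i + 1] + g[i + 1, i + 1]) / 4
}

#' The package's cached default digit classifier
#'
#' Trained on first use with a fixed seed and cached for the session.
#' @return a `digit_classifier`.
#' @export
default_digit_classifier <- function() {
  if (is.null(the$digit_classifier))
    the$digit_classifier <- train_digit_classifier()
  the$digit_classifier
}

#' Classify one digit glyph
#'
#' Normalizes the glyph (bounding-box crop, 20 px rescale, center-of-mass
#' placement in 28 x 28) and returns the argmax class with its probability.
#' The full class distribution is attached as attribute `"distribution"` and
#' sums to one.
#'
#' @param glyph binary/numeric ink raster.
#' @param classifier a `digit_classifier`; defaults to the cached one.
#' @return list with `digit` (0-9) and `confidence` in `[0, 1]`.
#' @export
classify_digit <- function(glyph, classifier = default_digit_classifier()) {
  if (max(glyph + 0) <= 0)
    iop_error("ClassificationError", "classify_digit: blank glyph")
  g <- normalize_glyph(glyph)
  p <- classifier$predict_glyph(g)
  i <- which.max(p)
  structure(list(digit = as.integer(names(p)[i]), confidence = unname(p[i])),
            distribution = p)
}

#' Segment the handwritten date into digit and delimiter regions
#'
#' Labels connected ink components inside the template's date region, orders
#' them left to right, and classifies each as digit or delimiter. A
#' component is a delimiter if its area is below 25% of the median digit
#' area or its aspect ratio is flatter than 1:2. Components substantially
#' wider than the median digit are flagged as possible merged digits.
#'
#' @param chart a `canonical_chart`.
#' @param template a [chart_template()] (default: the chart's).
#' @param ink_threshold gray level below which a pixel counts as ink.
#' @param min_px discard specks smaller than this.
#' @return list of regions, each with `box` (x1, y1, x2, y2), `glyph`
#'   (logical raster), `role` (`"digit"`/`"delimiter"`) and `warning`.
#' @export
segment_date_digits <- function(chart, template = chart$template,
                                ink_threshold = 0.55, min_px = 6L) {
  dr <- template$date_region
  gray <- to_gray(chart)
  sub <- gray[dr[2]:dr[4], dr[1]:dr[3], drop = FALSE] < ink_threshold
  lab <- label_components(sub)
  n <- max(lab)
  if (n == 0L) iop_error("DateNotFound", "segment_date_digits: empty date field")
  regs <- list()
  for (id in seq_len(n)) {
    ij <- which(lab == id, arr.ind = TRUE)
    if (nrow(ij) < min_px) next
    y1 <- min(ij[, 1]); y2 <- max(ij[, 1]); x1 <- min(ij[, 2]); x2 <- max(ij[, 2])
    glyph <- matrix(FALSE, y2 - y1 + 1L, x2 - x1 + 1L)
    glyph[cbind(ij[, 1] - y1 + 1L, ij[, 2] - x1 + 1L)] <- TRUE
    regs[[length(regs) + 1L]] <- list(
      box = c(x1 = x1 + dr[1] - 1L, y1 = y1 + dr[2] - 1L,
              x2 = x2 + dr[1] - 1L, y2 = y2 + dr[2] - 1L),
      glyph = glyph, area = nrow(ij),
      height = y2 - y1 + 1L, width = x2 - x1 + 1L)
  }
  if (length(regs) == 0L)
    iop_error("DateNotFound", "segment_date_digits: only specks in the date field")
  regs <- regs[order(vapply(regs, function(r) r$box["x1"], numeric(1)))]
  areas <- vapply(regs, `[[`, numeric(1), "area")
  aspect <- vapply(regs, function(r) r$height / r$width, numeric(1))
  med_digit_area <- stats::median(areas[aspect >= 0.5])
  if (is.na(med_digit_area)) med_digit_area <- stats::median(areas)
  widths <- vapply(regs, `[[`, numeric(1), "width")
  med_w <- stats::median(widths[aspect >= 0.5])
  for (i in seq_along(regs)) {
    delim <- regs[[i]]$area < 0.25 * med_digit_area || aspect[i] < 0.5
    regs[[i]]$role <- if (delim) "delimiter" else "digit"
    regs[[i]]$warning <- if (!delim && !is.na(med_w) && regs[[i]]$width > 1.7 * med_w)
      "double-width" else ""
  }
  regs
}

#' Assemble classified digits into a calendar date
#'
#' Groups the digit predictions by delimiter positions into
#' day.month.year (German convention), validates calendar legality, and
#' expands two-digit years against the plausible range (default 1950-2030:
#' `yy <= 30` becomes `20yy`, `yy >= 50` becomes `19yy`).
#'
#' @param regions output of [segment_date_digits()].
#' @param predictions list of [classify_digit()] results aligned with the
#'   digit regions (in order), or an integer vector of digits.
#' @param year_range plausible calendar years.
#' @return object of class `date_result`: `date` (a `Date`) and
#'   `confidence` (per-digit probabilities).
#' @export
parse_date <- function(regions, predictions, year_range = c(1950, 2030)) {
  roles <- vapply(regions, `[[`, character(1), "role")
  if (sum(roles == "delimiter") > 2L) {
    # keep the two most plausible delimiters (largest gaps stay digits)
    del <- which(roles == "delimiter")
    roles[del[-seq_len(2L)]] <- "digit"
  }
  if (is.numeric(predictions)) {
    digits <- as.integer(predictions)
    conf <- rep(NA_real_, length(digits))
  } else {
    digits <- vapply(predictions, function(p) p$digit, integer(1))
    conf <- vapply(predictions, function(p) p$confidence, numeric(1))
  }
  if (length(digits) != sum(roles == "digit"))
    iop_error("DateInvalid", "parse_date: predictions do not align with digit regions")
  grp <- cumsum(roles == "delimiter")[roles == "digit"] + 1L
  parts <- split(digits, grp)
  if (length(parts) == 1L && length(digits) %in% c(6L, 8L)) {
    # no delimiters segmented: fall back to positional D M Y split
    parts <- list(digits[1:2], digits[3:4], digits[5:length(digits)])
  }
  if (length(parts) != 3L)
    iop_error("DateInvalid", "parse_date: cannot group digits into day.month.year")
  num <- vapply(parts, function(d) sum(d * 10^(rev(seq_along(d)) - 1)), numeric(1))
  day <- num[1]; month <- num[2]; year <- num[3]
  if (length(parts[[3]]) == 2L)
    year <- if (year <= (year_range[2] %% 100)) 2000 + year else 1900 + year
  if (year < year_range[1] || year > year_range[2])
    iop_error("DateInvalid", sprintf("parse_date: year %d outside %d-%d",
                                     year, year_range[1], year_range[2]))
  date <- as.Date(sprintf("%04d-%02d-%02d", year, month, day), optional = TRUE)
  if (is.na(date) || month < 1 || month > 12)
    iop_error("DateInvalid", sprintf("parse_date: %02.0f.%02.0f.%04.0f is not a legal date",
                                     day, month, year))
  structure(list(date = date, confidence = conf), class = "date_result")
}

#' Read the date from a canonical chart
#'
#' Convenience wrapper: segment, classify every digit region, parse.
#'
#' @param chart a `canonical_chart`.
#' @param classifier a `digit_classifier`.
#' @param ... passed to [parse_date()].
#' @return a `date_result`.
#' @export
read_chart_date <- function(chart, classifier = default_digit_classifier(), ...) {
  regs <- segment_date_digits(chart)
  digs <- regs[vapply(regs, `[[`, character(1), "role") == "digit"]
  preds <- lapply(digs, function(r) classify_digit(r$glyph, classifier))
  parse_date(regs, preds, ...)
}

#' Find patient names in OCR text
#'
#' Applies a configurable pattern of the form "Capitalized-surname, comma,
#' Capitalized-given-name" (Unicode-aware, so umlauts and other diacritics
#' match) to text produced by an external OCR engine. The engine itself is
#' pluggable and not part of this package.
#'
#' @param ocr_text character scalar of recognized text.
#' @param pattern PCRE pattern with two capture groups (surname, given name).
#' @return object of class `name_result`: `raw_text` and `candidates` (data
#'   frame with `surname`, `given_name`), in reading order.
#' @export
extract_names <- function(ocr_text,
                          pattern = "(\\p{Lu}[\\p{L}'-]+)\\s*,\\s*(\\p{Lu}[\\p{L}'-]+)") {
  m <- gregexpr(pattern, ocr_text, perl = TRUE)
  hits <- regmatches(ocr_text, m)[[1]]
  if (length(hits) == 0L) {
    cand <- data.frame(surname = character(), given_name = character())
  } else {
    parts <- regmatches(hits, regexec(pattern, hits, perl = TRUE))
    cand <- data.frame(surname = vapply(parts, `[`, character(1), 2),
                       given_name = vapply(parts, `[`, character(1), 3))
  }
  structure(list(raw_text = ocr_text, candidates = cand), class = "name_result")
}

#' Pseudonymize a patient name
#'
#' Stable short hash of the normalized name, used in the output CSV unless
#' plain-text identifiers are explicitly requested (scanned charts carry
#' identifying stickers; outputs default to de-identified).
#'
#' @param name character vector.
#' @return character vector of 12-hex-digit pseudonyms.
#' @export
pseudonymize <- function(name) {
  if (requireNamespace("digest", quietly = TRUE)) {
    vapply(tolower(trimws(name)),
           function(x) substr(digest::digest(x, algo = "sha256"), 1, 12),
           character(1), USE.NAMES = FALSE)
  } else {
    # fallback: deterministic base-36 of a simple polynomial hash
    vapply(tolower(trimws(name)), function(x) {
      h <- 0
      for (c in utf8ToInt(x)) h <- (h * 131 + c) %% 2^48
      sprintf("%012x", h)
    }, character(1), USE.NAMES = FALSE)
  }
}
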