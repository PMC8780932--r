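# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: per-pixel loops and plain-formula arithmetic only.

# Confusion counts by an explicit per-pixel double loop.
naive_confusion <- function(pred, ref) {
  tp <- 0L; fp <- 0L; fn <- 0L; tn <- 0L
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      p <- pred[i, j]; r <- ref[i, j]
      if (p && r) tp <- tp + 1L
      else if (p && !r) fp <- fp + 1L
      else if (!p && r) fn <- fn + 1L
      else tn <- tn + 1L
    }
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# Metrics from counts, written out directly from their definitions.
naive_metrics <- function(n) {
  tp <- n$tp; fp <- n$fp; fn <- n$fn; tn <- n$tn
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  acc <- (tp + tn) / (tp + fp + fn + tn)
  j <- if (is.na(sens) || is.na(spec)) NA_real_ else sens + spec - 1
  f <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  d <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  m <- if (d == 0) 0 else
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(d)
  list(sensitivity = sens, specificity = spec, precision = prec,
       accuracy = acc, youden_j = j, f_score = f, mcc = m)
}

# Naive binary erosion/dilation with an arbitrary structuring element
# (odd-sized 0/1 matrix). Border convention: out-of-image pixels count as
# foreground for erosion and background for dilation, so borders do not
# shrink — the same convention as the package's morphology.
naive_morph <- function(mask, brush, op = c("erode", "dilate")) {
  op <- match.arg(op)
  h <- nrow(mask); w <- ncol(mask)
  rb <- (nrow(brush) - 1L) / 2L; cb <- (ncol(brush) - 1L) / 2L
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    vals <- logical(0)
    for (di in -rb:rb) for (dj in -cb:cb) {
      if (brush[di + rb + 1L, dj + cb + 1L] == 0) next
      ii <- i + di; jj <- j + dj
      v <- if (ii >= 1L && ii <= h && jj >= 1L && jj <= w) mask[ii, jj]
      else op == "erode"
      vals <- c(vals, v)
    }
    out[i, j] <- if (op == "erode") all(vals) else any(vals)
  }
  out
}

# Strip mask attributes down to a plain logical matrix for content
# comparisons.
mval <- function(m) matrix(as.logical(m), nrow(m), ncol(m))

# Random logical matrix with a given on-probability.
random_mask <- function(h, w, p = 0.5) {
  matrix(stats::runif(h * w) < p, h, w)
}

# Random simple-ish polygon: points on a circle with jittered radii,
# vertex coordinates avoiding half-integers so pixel centers never sit
# exactly on an edge.
random_polygon <- function(grid = 32, n_min = 3, n_max = 8) {
  n <- sample(n_min:n_max, 1)
  cx <- stats::runif(1, 4, grid - 4)
  cy <- stats::runif(1, 4, grid - 4)
  ang <- sort(stats::runif(n, 0, 2 * pi))
  rad <- stats::runif(n, 1, grid / 3)
  cbind(cx + rad * cos(ang), cy + rad * sin(ang))
}

# A tiny uniform image of one color.
uniform_image <- function(h, w, color, id = "uniform") {
  px <- array(0L, dim = c(h, w, 3L))
  for (ch in 1:3) px[, , ch] <- color[ch]
  rgb_image(px, id = id)
}
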