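#' Specification for a synthetic histology-like image
#'
#' Describes a deterministic test image: a noisy tissue-colored
#' background, optional near-white slide margin, and one or more positive
#' feature classes (elliptical droplets or star-convex blobs) painted
#' with per-pixel color noise. Pixel-exact ground-truth masks are
#' recorded at paint time, so every downstream module can be validated
#' without real slides. The generator emulates brightfield staining
#' scenarios (fat vacuoles, collagen, vessel obstructions, brown/blue
#' nuclei); it makes no attempt at photorealistic texture.
#'
#' @param width,height Image size in pixels.
#' @param seed Default RNG seed used by [generate_synthetic()].
#' @param background Color model for tissue background:
#'   `list(type = "uniform", color = c(r, g, b), spread = s)` draws each
#'   channel uniformly from `color +/- spread` (clamped to `[0, 255]`);
#'   see Details for the blended band models.
#' @param slide_margin Near-white border width in pixels (0 = none).
#' @param classes Named list of feature classes, each a list with:
#'   `color_model` (as `background`), `shape` (`"ellipse"` or `"blob"`),
#'   `count` (number of features; ignored when `target_area_fraction` is
#'   set), `size_range` (equivalent-radius range in pixels),
#'   `overlap` (allow same-class overlap), and optional
#'   `target_area_fraction` in `[0, 1]` (features are added until the
#'   class truth area reaches it).
#'
#' @details Two blended color models exercise classifiers whose positive
#' colors are not axis-aligned in RGB space:
#' `list(type = "rg_band", r_range =, band_sum =, halfwidth =, b_range =)`
#' draws red uniformly and sets green to `band_sum - r` plus a jitter of
#' at most `halfwidth`, so positive colors lie on an anti-diagonal band;
#' `list(type = "rg_band_complement", r_range =, g_range =, band_sum =,
#' gap =, b_range =)` draws (r, g) uniformly but rejects pairs within
#' `gap` of the band, producing a background that overlaps the band
#' colors in every single-channel marginal while staying disjoint from
#' them in joint RGB space.
#'
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(width = 256L, height = 256L, seed = 1L,
                           background = list(type = "uniform",
                                             color = c(230, 205, 150),
                                             spread = 8),
                           slide_margin = 0L,
                           classes = list()) {
  if (width < 8L || height < 8L)
    stop("image must be at least 8 x 8", call. = FALSE)
  if (slide_margin < 0L || 2L * slide_margin >= min(width, height))
    stop("slide_margin leaves no interior", call. = FALSE)
  if (is.null(names(classes)) && length(classes))
    stop("`classes` must be a named list", call. = FALSE)
  classes <- lapply(classes, function(cl) {
    cl$shape <- if (is.null(cl$shape)) "ellipse" else cl$shape
    if (!cl$shape %in% c("ellipse", "blob"))
      stop("shape must be 'ellipse' or 'blob'", call. = FALSE)
    if (is.null(cl$count)) cl$count <- 20L
    if (is.null(cl$size_range)) cl$size_range <- c(4, 10)
    if (is.null(cl$overlap)) cl$overlap <- TRUE
    check_color_model(cl$color_model)
    cl
  })
  check_color_model(background)
  structure(list(width = as.integer(width), height = as.integer(height),
                 seed = as.integer(seed), background = background,
                 slide_margin = as.integer(slide_margin),
                 classes = classes),
            class = "synthetic_spec")
}

check_color_model <- function(m) {
  if (is.null(m$type)) stop("color model needs a `type`", call. = FALSE)
  if (m$type == "uniform") {
    if (length(m$color) != 3L || min(m$color) < 0 || max(m$color) > 255)
      stop("uniform color model needs color = c(r, g, b) in [0,255]",
           call. = FALSE)
    if (is.null(m$spread) || m$spread < 0)
      stop("uniform color model needs spread >= 0", call. = FALSE)
  } else if (!m$type %in% c("rg_band", "rg_band_complement")) {
    stop("unknown color model type: ", m$type, call. = FALSE)
  }
  invisible(m)
}

clamp255 <- function(x) {
  v <- pmin(pmax(round(x), 0), 255)  # keeps dim attributes
  storage.mode(v) <- "integer"
  v
}

# Draw n RGB colors from a color model; returns an n x 3 integer matrix.
sample_colors <- function(model, n) {
  unif_int <- function(lo, hi, n) {
    if (lo == hi) rep.int(as.integer(lo), n)
    else sample(seq.int(lo, hi), n, replace = TRUE)
  }
  if (model$type == "uniform") {
    s <- model$spread
    out <- sapply(1:3, function(ch)
      clamp255(model$color[ch] + unif_int(-s, s, n)))
    matrix(out, ncol = 3L)
  } else if (model$type == "rg_band") {
    r <- unif_int(model$r_range[1], model$r_range[2], n)
    g <- clamp255(model$band_sum - r +
                    unif_int(-model$halfwidth, model$halfwidth, n))
    b <- unif_int(model$b_range[1], model$b_range[2], n)
    cbind(r, g, b, deparse.level = 0)
  } else if (model$type == "rg_band_complement") {
    r <- unif_int(model$r_range[1], model$r_range[2], n)
    g <- unif_int(model$g_range[1], model$g_range[2], n)
    for (it in 1:100) {
      bad <- abs(r + g - model$band_sum) < model$gap
      if (!any(bad)) break
      g[bad] <- unif_int(model$g_range[1], model$g_range[2], sum(bad))
    }
    b <- unif_int(model$b_range[1], model$b_range[2], n)
    cbind(r, g, b, deparse.level = 0)
  } else stop("unknown color model type: ", model$type, call. = FALSE)
}

# Pixel set (linear indices into an h x w matrix) of one random feature
# centered at (cx, cy) in 0-based pixel coordinates, radius r.
feature_pixels <- function(shape, cx, cy, r, h, w) {
  ext <- ceiling(r * 1.45) + 1L
  ii <- max(0L, floor(cy - ext)):min(h - 1L, ceiling(cy + ext))
  jj <- max(0L, floor(cx - ext)):min(w - 1L, ceiling(cx + ext))
  px <- rep(jj + 0.5, each = length(ii)) - cx
  py <- rep(ii + 0.5, times = length(jj)) - cy
  if (shape == "ellipse") {
    e <- stats::runif(1, 0.7, 1.3)
    th <- stats::runif(1, 0, pi)
    a <- r * e; b <- r / e
    xr <- px * cos(th) + py * sin(th)
    yr <- -px * sin(th) + py * cos(th)
    inside <- (xr / a)^2 + (yr / b)^2 <= 1
  } else {
    # star-convex blob: radius modulated by low-order harmonics
    amp <- 0.3
    ck <- stats::runif(3, -1, 1)
    ps <- stats::runif(3, 0, 2 * pi)
    ang <- atan2(py, px)
    mod <- rep(0, length(ang))
    for (k in 1:3) mod <- mod + ck[k] * cos((k + 1) * ang + ps[k])
    mod <- mod / 3
    inside <- sqrt(px^2 + py^2) <= r * (1 + amp * mod)
  }
  idx <- which(inside)
  i <- ii[(idx - 1L) %% length(ii) + 1L]
  j <- jj[(idx - 1L) %/% length(ii) + 1L]
  i + 1L + j * h  # linear index, column-major
}

#' Generate a synthetic image with pixel-exact ground truth
#'
#' Paints, in order: the noisy background, then each class's features
#' (per-pixel color noise; truth masks recorded from the exact painted
#' pixel sets), then the near-white slide margin. Features are placed
#' entirely inside the non-margin interior, never overwrite another
#' class's truth pixels, and same-class overlap follows the class's
#' `overlap` flag. Identical spec and seed give bit-identical output.
#'
#' @param spec A [synthetic_spec].
#' @param seed RNG seed; defaults to `spec$seed`.
#' @param id Image identifier; default derived from the seed.
#' @return List with `image` (an [rgb_image]), `truth` (named list of
#'   [binary_mask]s, one per class), and `metadata` (realized per-class
#'   area fractions, feature draws, seed).
#' @export
generate_synthetic <- function(spec, seed = spec$seed,
                               id = sprintf("sim_%d", seed)) {
  stopifnot(inherits(spec, "synthetic_spec"))
  h <- spec$height; w <- spec$width; m <- spec$slide_margin
  interior <- (h - 2L * m) * (w - 2L * m)
  targets <- vapply(spec$classes, function(cl)
    if (is.null(cl$target_area_fraction)) 0 else cl$target_area_fraction,
    numeric(1))
  if (sum(targets) > 0.8 * interior / (h * w))
    stop("infeasible spec: requested area fractions exceed 80% of the ",
         "paintable interior", call. = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)

  px <- sample_colors(spec$background, h * w)
  img <- array(0L, dim = c(h, w, 3L))
  for (ch in 1:3) img[, , ch] <- matrix(px[, ch], h, w)

  truth <- list()
  any_truth <- matrix(FALSE, h, w)
  feats <- list()
  for (cname in names(spec$classes)) {
    cl <- spec$classes[[cname]]
    tm <- matrix(FALSE, h, w)
    target_px <- if (is.null(cl$target_area_fraction)) NA_real_
    else cl$target_area_fraction * h * w
    n_placed <- 0L; attempts <- 0L
    max_attempts <- 50000L
    repeat {
      done <- if (is.na(target_px)) n_placed >= cl$count
      else sum(tm) >= target_px
      if (done || attempts >= max_attempts) break
      attempts <- attempts + 1L
      r <- stats::runif(1, cl$size_range[1], cl$size_range[2])
      pad <- r * 1.45 + 1
      if (w - m - pad <= m + pad || h - m - pad <= m + pad) next
      cx <- stats::runif(1, m + pad, w - m - pad)
      cy <- stats::runif(1, m + pad, h - m - pad)
      idx <- feature_pixels(cl$shape, cx, cy, r, h, w)
      if (!length(idx)) next
      other <- any_truth[idx] & !tm[idx]
      if (any(other)) next                       # never cross classes
      if (!cl$overlap && any(tm[idx])) next
      cols <- sample_colors(cl$color_model, length(idx))
      for (ch in 1:3) {
        plane <- img[, , ch]; plane[idx] <- cols[, ch]; img[, , ch] <- plane
      }
      tm[idx] <- TRUE; any_truth[idx] <- TRUE
      n_placed <- n_placed + 1L
      feats[[length(feats) + 1L]] <- data.frame(
        class = cname, shape = cl$shape, cx = cx, cy = cy, r = r,
        area = length(idx))
    }
    if (!is.na(target_px) && sum(tm) < target_px && attempts >= max_attempts)
      stop("could not reach target area fraction for class ", cname,
           call. = FALSE)
    truth[[cname]] <- tm
  }
  if (m > 0L) {
    border <- matrix(FALSE, h, w)
    border[c(1:m, (h - m + 1L):h), ] <- TRUE
    border[, c(1:m, (w - m + 1L):w)] <- TRUE
    nwhite <- sum(border)
    cols <- clamp255(matrix(248L, nwhite, 3L) +
                       matrix(sample(seq.int(-4L, 4L), nwhite * 3L,
                                     replace = TRUE), nwhite, 3L))
    for (ch in 1:3) {
      plane <- img[, , ch]; plane[border] <- cols[, ch]; img[, , ch] <- plane
    }
    for (cname in names(truth)) truth[[cname]][border] <- FALSE
  }
  truth_masks <- lapply(names(truth), function(cn)
    binary_mask(truth[[cn]], image_id = id, class_name = cn))
  names(truth_masks) <- names(truth)
  realized <- vapply(truth, function(tm) mean(tm), numeric(1))
  list(image = rgb_image(img, id = id),
       truth = truth_masks,
       metadata = list(id = id, seed = seed, width = w, height = h,
                       slide_margin = m,
                       realized_area_fraction = as.list(realized),
                       features = if (length(feats)) do.call(rbind, feats)
                       else data.frame()))
}

#' Generate training images with polygon annotations
#'
#' Emits a small set of training images drawn from the same spec
#' (distinct derived seeds) together with annotations suitable for
#' [accumulate_training()]: positive polygons inscribed inside sampled
#' feature interiors (shrunk inward to avoid boundary color mixing) and
#' negative rectangles over clean background patches, plus a near-white
#' margin patch when the spec has one.
#'
#' @param spec A [synthetic_spec].
#' @param seed Base seed; image k uses `seed * 10 + k`.
#' @param n_images Number of training images (default 2).
#' @param max_features_per_class Positive polygons sampled per class per
#'   image (largest features first). The default of 12 keeps the sampled
#'   regions representative of a class's color variation even when its
#'   features are small; too few, too-small polygons under-sample the
#'   color distribution and the trained palette undercalls the class.
#' @return List with `images` (list of [rgb_image]), `annotations`
#'   (list of [region_annotation]), and `fixtures` (the full
#'   [generate_synthetic()] results, for truth access in tests).
#' @export
generate_training_pair <- function(spec, seed = spec$seed, n_images = 2L,
                                   max_features_per_class = 12L) {
  # patch sampling below draws from the RNG too; pin it so the whole
  # training set is reproducible from `seed` alone
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)
  fixtures <- lapply(seq_len(n_images), function(k)
    generate_synthetic(spec, seed = seed * 10L + k,
                       id = sprintf("train_%d_%d", seed, k)))
  annotations <- list()
  for (fx in fixtures) {
    img <- fx$image
    h <- spec$height; w <- spec$width
    feats <- fx$metadata$features
    for (cname in names(spec$classes)) {
      cf <- if (nrow(feats)) feats[feats$class == cname, , drop = FALSE]
      else feats
      if (!nrow(cf)) next
      take <- utils::head(order(-cf$area), max_features_per_class)
      for (i in take) {
        poly <- inscribed_polygon(cf$cx[i], cf$cy[i], cf$r[i],
                                  spec$classes[[cname]]$shape)
        tr <- unclass(fx$truth[[cname]])
        # shrink until the polygon's pixels are pure class truth
        ok <- FALSE
        for (shrink in c(1, 0.7, 0.5)) {
          p <- sweep(sweep(poly, 2, c(cf$cx[i], cf$cy[i])), 2,
                     c(shrink, shrink), `*`)
          p <- sweep(p, 2, c(cf$cx[i], cf$cy[i]), `+`)
          ras <- rasterize_polygon(p, h, w)
          if (any(ras) && all(tr[ras])) { ok <- TRUE; poly <- p; break }
        }
        if (ok)
          annotations[[length(annotations) + 1L]] <-
            region_annotation(img$id, cname, poly)
      }
    }
    annotations <- c(annotations,
                     negative_patches(fx, spec, max_patches = 8L))
  }
  list(images = lapply(fixtures, `[[`, "image"),
       annotations = annotations,
       fixtures = fixtures)
}

# Polygon inscribed in a feature of radius r at (cx, cy): a 12-gon on a
# circle comfortably inside the shape (ellipses have semi-minor axis
# >= r / 1.3; blobs have radius >= 0.7 r), pulled 1.5 px further in.
inscribed_polygon <- function(cx, cy, r, shape) {
  rin <- max(0.8, if (shape == "ellipse") r / 1.35 - 1.5 else 0.65 * r - 1.5)
  t <- seq(0, 2 * pi, length.out = 13L)[-13L]
  cbind(cx + rin * cos(t), cy + rin * sin(t))
}

# Negative annotations: square background patches containing no truth
# pixels (2 px safety pad), scanned on a grid; plus one margin patch.
negative_patches <- function(fx, spec, side = 10L, max_patches = 8L) {
  h <- spec$height; w <- spec$width; m <- spec$slide_margin
  any_truth <- Reduce(`|`, lapply(fx$truth, unclass),
                      matrix(FALSE, h, w))
  out <- list()
  stride <- side + 6L
  ys <- seq(m + 3L, h - m - side - 3L, by = stride)
  xs <- seq(m + 3L, w - m - side - 3L, by = stride)
  cand <- expand.grid(x = xs, y = ys)
  cand <- cand[sample.int(nrow(cand)), , drop = FALSE]
  for (i in seq_len(nrow(cand))) {
    if (length(out) >= max_patches) break
    x <- cand$x[i]; y <- cand$y[i]
    rows <- (y - 2L):(y + side + 2L) + 1L
    cols <- (x - 2L):(x + side + 2L) + 1L
    rows <- rows[rows >= 1 & rows <= h]; cols <- cols[cols >= 1 & cols <= w]
    if (any(any_truth[rows, cols])) next
    out[[length(out) + 1L]] <- region_annotation(
      fx$image$id, "negative",
      cbind(c(x, x + side, x + side, x), c(y, y, y + side, y + side)))
  }
  if (m >= side) {
    out[[length(out) + 1L]] <- region_annotation(
      fx$image$id, "negative",
      cbind(c(1, m - 1, m - 1, 1), c(1, 1, h - 1, h - 1)))
  }
  out
}

#' Named synthetic presets for common staining scenarios
#'
#' Illustrative color presets (not calibrated to real stains):
#' `"sirius_red"` — red collagen blobs on pale yellow;
#' `"he_obstruction"` — pink occlusions on pale purple tissue;
#' `"steatosis"` — near-white fat droplets on pink tissue;
#' `"tunel"` — brown (DAB) and blue (hematoxylin) nuclei, two classes;
#' `"blend"` — anti-diagonal blended positive colors whose single-channel
#' marginals overlap the background (the box-threshold stress case).
#'
#' @param name Preset name.
#' @param width,height,seed Passed to [synthetic_spec()].
#' @param ... Overrides merged into the preset's class list.
#' @return A [synthetic_spec].
#' @export
synthetic_preset <- function(name = c("sirius_red", "he_obstruction",
                                      "steatosis", "tunel", "blend"),
                             width = 256L, height = 256L, seed = 1L, ...) {
  name <- match.arg(name)
  u <- function(color, spread) list(type = "uniform", color = color,
                                    spread = spread)
  spec_args <- switch(
    name,
    sirius_red = list(
      background = u(c(230, 205, 150), 8),
      classes = list(collagen = list(
        color_model = u(c(185, 70, 60), 8), shape = "blob",
        count = 25L, size_range = c(4, 12)))),
    he_obstruction = list(
      background = u(c(205, 170, 205), 8),
      classes = list(obstruction = list(
        color_model = u(c(235, 140, 150), 6), shape = "blob",
        count = 12L, size_range = c(6, 16)))),
    steatosis = list(
      background = u(c(235, 180, 190), 8),
      classes = list(steatosis = list(
        color_model = u(c(250, 250, 250), 3), shape = "ellipse",
        count = 40L, size_range = c(3, 10), overlap = FALSE))),
    tunel = list(
      background = u(c(228, 215, 232), 6),
      classes = list(
        brown = list(color_model = u(c(130, 90, 55), 8),
                     shape = "ellipse", size_range = c(3, 7),
                     target_area_fraction = 0.016),
        blue = list(color_model = u(c(80, 95, 170), 8),
                    shape = "ellipse", size_range = c(3, 7),
                    target_area_fraction = 0.10))),
    blend = list(
      background = list(type = "rg_band_complement",
                        r_range = c(60, 220), g_range = c(60, 220),
                        band_sum = 280, gap = 40, b_range = c(90, 110)),
      classes = list(blend_positive = list(
        color_model = list(type = "rg_band", r_range = c(80, 200),
                           band_sum = 280, halfwidth = 16,
                           b_range = c(90, 110)),
        shape = "ellipse", count = NULL, size_range = c(5, 14),
        target_area_fraction = 0.2))))
  extra <- list(...)
  for (nm in names(extra)) spec_args[[nm]] <- extra[[nm]]
  do.call(synthetic_spec,
          c(list(width = width, height = height, seed = seed), spec_args))
}

#' Write a synthetic fixture set to disk
#'
#' Writes the image as PNG, one truth PNG per class, a metadata JSON and
#' a manifest (`manifest.json`) listing every file with its MD5 hash for
#' reproducibility checks.
#'
#' @param fixture Result of [generate_synthetic()].
#' @param out_dir Output directory (created if needed).
#' @param annotations Optional annotations to write alongside
#'   (`annotations.json`).
#' @return Paths of all written files, invisibly.
#' @export
write_fixture_set <- function(fixture, out_dir, annotations = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  id <- fixture$metadata$id
  paths <- character(0)
  p <- file.path(out_dir, paste0(id, ".png"))
  write_image_png(fixture$image, p); paths <- c(paths, p)
  for (cn in names(fixture$truth)) {
    p <- file.path(out_dir, paste0(id, "_truth_", cn, ".png"))
    write_mask_png(fixture$truth[[cn]], p); paths <- c(paths, p)
  }
  meta <- fixture$metadata
  meta$features <- NULL  # keep the JSON small; draws live in R only
  p <- file.path(out_dir, paste0(id, "_metadata.json"))
  jsonlite::write_json(meta, p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)
  if (!is.null(annotations)) {
    p <- file.path(out_dir, "annotations.json")
    write_annotations(annotations, p); paths <- c(paths, p)
  }
  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE)
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, mp))
}
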