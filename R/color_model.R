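#' Quantize an RGB color into uniform per-channel bins
#'
#' The trained color map lives on a discretized RGB cube: each channel is
#' divided into `levels` uniform bins over `[0, 255]` and a color is
#' represented by its triple of bin indices, `floor(channel * levels / 256)`.
#' With `levels = 64` (the default throughout the package) bins are 4 values
#' wide, which absorbs sensor noise while keeping visually distinct shades
#' apart.
#'
#' @param color Integer vector `c(r, g, b)` in `[0, 255]`, or an `n x 3`
#'   matrix of colors.
#' @param levels Number of bins per channel, in `[2, 256]`.
#' @return Integer bin indices, same shape as the input, each in
#'   `[0, levels - 1]`.
#' @export
quantize_color <- function(color, levels = 64L) {
  check_levels(levels)
  if (is.null(dim(color))) {
    stopifnot(length(color) == 3L)
    color <- matrix(color, ncol = 3L)
    drop1 <- TRUE
  } else drop1 <- FALSE
  if (min(color) < 0 || max(color) > 255)
    stop("channel values must lie in [0, 255]", call. = FALSE)
  q <- matrix(as.integer(floor(color * levels / 256)), ncol = 3L)
  if (drop1) q[1L, ] else q
}

check_levels <- function(levels) {
  if (length(levels) != 1L || is.na(levels) || levels < 2 || levels > 256)
    stop("`levels` must be a single integer in [2, 256]", call. = FALSE)
  invisible(as.integer(levels))
}

# Pack (rq, gq, bq) bin indices into a single integer key (levels <= 256
# keeps keys below 2^24). Keys are the sparse index of the color map.
color_key <- function(q, levels) {
  (q[, 1L] * levels + q[, 2L]) * levels + q[, 3L]
}

key_to_bins <- function(key, levels) {
  b <- key %% levels
  key <- key %/% levels
  g <- key %% levels
  r <- key %/% levels
  cbind(r, g, b)
}

# H*W x 3 integer matrix of pixel colors, row-major over the H x W grid
# (R's column-major order of the pixel matrix; consistent everywhere).
pixel_matrix <- function(image) {
  px <- image$pixels
  d <- dim(px)
  dim(px) <- c(d[1] * d[2], 3L)
  px
}

image_keys <- function(image, levels) {
  color_key(quantize_color(pixel_matrix(image), levels), levels)
}

#' Create a polygon region annotation
#'
#' Annotations carry the training signal: a labeled polygon drawn on a
#' training image. Coordinates are 0-based pixel coordinates with the
#' origin at the top-left corner; `x` runs along columns, `y` along rows.
#'
#' @param image_id Identifier of the annotated image.
#' @param label Class name: one of the declared positive classes, or the
#'   reserved name `"negative"`.
#' @param polygon Numeric `n x 2` matrix (columns x, y) or list of
#'   `c(x, y)` pairs, with at least 3 vertices.
#' @return An object of class `region_annotation`.
#' @export
region_annotation <- function(image_id, label, polygon) {
  if (is.list(polygon)) polygon <- do.call(rbind, polygon)
  polygon <- matrix(as.numeric(polygon), ncol = 2L)
  if (nrow(polygon) < 3L)
    stop("polygon needs at least 3 vertices", call. = FALSE)
  structure(list(image_id = as.character(image_id),
                 label = as.character(label),
                 polygon = polygon),
            class = "region_annotation")
}

#' Rasterize a polygon annotation onto an image grid
#'
#' A pixel at 0-based row `i`, column `j` has center `(j + 0.5, i + 0.5)`.
#' The pixel belongs to the region when its center is inside the polygon
#' under the even-odd rule, implemented as a leftward ray-crossing test
#' with strict inequalities. For polygons with integer vertex coordinates
#' this yields half-open behavior (left/top edges included, right/bottom
#' excluded), so abutting polygons never double-count a pixel. All counts
#' in the color map depend on this convention, which is fixed.
#'
#' @param annotation A [region_annotation].
#' @param image The [rgb_image] it refers to (for shape and id check).
#' @return A [binary_mask], `TRUE` inside the polygon.
#' @export
rasterize_region <- function(annotation, image) {
  stopifnot(inherits(annotation, "region_annotation"),
            inherits(image, "rgb_image"))
  if (annotation$image_id != image$id)
    stop(sprintf("annotation refers to '%s' but image is '%s'",
                 annotation$image_id, image$id), call. = FALSE)
  d <- dim(image$pixels)
  m <- rasterize_polygon(annotation$polygon, d[1], d[2])
  if (!any(m))
    stop("polygon covers no pixel centers (empty or out-of-bounds region)",
         call. = FALSE)
  binary_mask(m, image_id = image$id, class_name = annotation$label)
}

# Even-odd rasterization over pixel centers, vectorized over the polygon's
# bounding box. Returns a full H x W logical matrix.
rasterize_polygon <- function(poly, h, w) {
  out <- matrix(FALSE, h, w)
  i0 <- max(0L, floor(min(poly[, 2]) - 0.5))
  i1 <- min(h - 1L, ceiling(max(poly[, 2])))
  j0 <- max(0L, floor(min(poly[, 1]) - 0.5))
  j1 <- min(w - 1L, ceiling(max(poly[, 1])))
  if (i0 > i1 || j0 > j1) return(out)
  jj <- j0:j1; ii <- i0:i1
  px <- rep(jj + 0.5, each = length(ii))
  py <- rep(ii + 0.5, times = length(jj))
  inside <- rep(FALSE, length(px))
  n <- nrow(poly)
  for (k in seq_len(n)) {
    x1 <- poly[k, 1]; y1 <- poly[k, 2]
    k2 <- if (k == n) 1L else k + 1L
    x2 <- poly[k2, 1]; y2 <- poly[k2, 2]
    crosses <- (y1 > py) != (y2 > py)
    if (any(crosses)) {
      xint <- x1 + (x2 - x1) * (py[crosses] - y1) / (y2 - y1)
      hit <- which(crosses)[px[crosses] < xint]
      inside[hit] <- !inside[hit]
    }
  }
  out[ii + 1L, jj + 1L] <- matrix(inside, nrow = length(ii))
  out
}

#' Accumulate a color training table from annotated regions
#'
#' Builds the color map: for every pixel inside an annotated region, the
#' occurrence count of the pixel's quantized color under the region's
#' label is incremented once per (pixel, region) membership. Pixels
#' covered by no region contribute nothing; a pixel inside two regions of
#' different labels increments both counts, so conflicting annotations
#' soften the model rather than invalidate it.
#'
#' @param images List of [rgb_image] objects (or a single one).
#' @param annotations List of [region_annotation] objects.
#' @param levels Quantization levels per channel (see [quantize_color]).
#' @param classes Declared positive class names; defaults to all non-
#'   `"negative"` labels found in the annotations.
#' @return A `color_training_table`: list with `levels`, `classes`,
#'   `keys` (sparse quantized-color keys), `counts` (one column per
#'   positive class plus `"negative"`), and `total_pixels`.
#' @export
accumulate_training <- function(images, annotations, levels = 64L,
                                classes = NULL) {
  levels <- check_levels(levels)
  if (inherits(images, "rgb_image")) images <- list(images)
  if (inherits(annotations, "region_annotation")) annotations <- list(annotations)
  labels <- vapply(annotations, function(a) a$label, "")
  if (is.null(classes)) classes <- sort(unique(labels[labels != "negative"]))
  if (length(classes) == 0L || !any(labels %in% classes))
    stop("training insufficiency: no positive regions supplied", call. = FALSE)
  if (!any(labels == "negative"))
    stop("training insufficiency: no negative regions supplied", call. = FALSE)
  unknown <- setdiff(labels, c(classes, "negative"))
  if (length(unknown))
    stop("annotation label(s) not in declared classes: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  ids <- vapply(images, function(im) im$id, "")
  cols <- c(classes, "negative")
  acc <- list()
  for (a in annotations) {
    idx <- match(a$image_id, ids)
    if (is.na(idx))
      stop("annotation refers to unknown image: ", a$image_id, call. = FALSE)
    img <- images[[idx]]
    m <- rasterize_region(a, img)
    keys <- image_keys(img, levels)[as.vector(m)]
    tab <- table(keys)
    acc[[length(acc) + 1L]] <- data.frame(
      key = as.numeric(names(tab)),
      label = a$label,
      n = as.integer(tab))
  }
  df <- do.call(rbind, acc)
  keys <- sort(unique(df$key))
  counts <- matrix(0, nrow = length(keys), ncol = length(cols),
                   dimnames = list(NULL, cols))
  for (lab in unique(df$label)) {
    sub <- df[df$label == lab, ]
    agg <- tapply(sub$n, sub$key, sum)
    counts[match(as.numeric(names(agg)), keys), lab] <-
      counts[match(as.numeric(names(agg)), keys), lab] + as.numeric(agg)
  }
  new_training_table(levels, classes, keys, counts)
}

new_training_table <- function(levels, classes, keys, counts) {
  structure(list(levels = as.integer(levels),
                 classes = as.character(classes),
                 keys = as.numeric(keys),
                 counts = counts,
                 total_pixels = sum(counts)),
            class = "color_training_table")
}

#' @export
print.color_training_table <- function(x, ...) {
  cat(sprintf("<color_training_table: %d colors, levels=%d, %s pixels>\n",
              length(x$keys), x$levels, format(x$total_pixels, big.mark = ",")))
  for (cl in colnames(x$counts))
    cat(sprintf("  %-12s %s pixels\n", cl,
                format(sum(x$counts[, cl]), big.mark = ",")))
  invisible(x)
}

#' Merge two color training tables
#'
#' Entrywise sum of occurrence counts; the sparse color entries are
#' unioned. Merging a second-pass table into the first implements
#' palette re-training with an updated color map. The operation is
#' commutative and associative.
#'
#' @param base,update `color_training_table`s with identical `levels` and
#'   class declarations.
#' @return The merged `color_training_table`.
#' @export
merge_training <- function(base, update) {
  stopifnot(inherits(base, "color_training_table"),
            inherits(update, "color_training_table"))
  if (base$levels != update$levels)
    stop("cannot merge tables with different quantization levels", call. = FALSE)
  if (!identical(base$classes, update$classes))
    stop("cannot merge tables with different class declarations", call. = FALSE)
  keys <- sort(unique(c(base$keys, update$keys)))
  cols <- colnames(base$counts)
  counts <- matrix(0, length(keys), length(cols), dimnames = list(NULL, cols))
  counts[match(base$keys, keys), ] <- base$counts
  iu <- match(update$keys, keys)
  counts[iu, ] <- counts[iu, ] + update$counts
  new_training_table(base$levels, base$classes, keys, counts)
}

#' Derive the positive-color palette from a training table
#'
#' Turns the color map into the decision rule: a quantized color joins a
#' positive class's color list when that class's share of all the color's
#' training occurrences strictly exceeds `threshold`. With several
#' positive classes a color can satisfy the rule for at most one class
#' (the rule requires a strict majority share against *all* other counts
#' combined); it is assigned to the class with the largest count, and the
#' positive color lists are therefore disjoint. Colors never observed in
#' training are resolved at classification time by `unseen_policy`.
#'
#' @param table A `color_training_table`.
#' @param threshold Positive-fraction cutoff in `(0, 1]`; default `0.5`
#'   (strict majority).
#' @param unseen_policy `"negative"` (default: novel colors are negative)
#'   or `"nearest"` (label of the nearest observed quantized color by
#'   Euclidean distance in bin-index space; ties resolve to negative).
#' @return A `stain_palette`: list with `levels`, `threshold`, `classes`,
#'   `positive` (per class, quantized color keys), `unseen_policy`, and
#'   the observed colors with their assigned labels (for the nearest
#'   policy).
#' @export
derive_palette <- function(table, threshold = 0.5,
                           unseen_policy = c("negative", "nearest")) {
  stopifnot(inherits(table, "color_training_table"))
  unseen_policy <- match.arg(unseen_policy)
  if (length(threshold) != 1L || threshold <= 0 || threshold > 1)
    stop("`threshold` must lie in (0, 1]", call. = FALSE)
  if (length(table$keys) == 0L) stop("empty training table", call. = FALSE)
  counts <- table$counts[, table$classes, drop = FALSE]
  totals <- rowSums(table$counts)
  # winner = positive class with the largest count for each color
  win <- max.col(counts, ties.method = "first")
  frac <- counts[cbind(seq_along(win), win)] / totals
  assigned <- ifelse(frac > threshold, win, 0L)
  positive <- lapply(seq_along(table$classes), function(k)
    table$keys[assigned == k])
  names(positive) <- table$classes
  if (all(assigned == 0L))
    stop("empty palette: no color passes the positive threshold; ",
         "lower the threshold or add positive training regions",
         call. = FALSE)
  structure(list(levels = table$levels,
                 threshold = threshold,
                 classes = table$classes,
                 positive = positive,
                 unseen_policy = unseen_policy,
                 observed_keys = table$keys,
                 observed_labels = as.integer(assigned)),
            class = "stain_palette")
}

#' @export
print.stain_palette <- function(x, ...) {
  cat(sprintf("<stain_palette: levels=%d, threshold=%g, policy=%s>\n",
              x$levels, x$threshold, x$unseen_policy))
  for (cl in x$classes)
    cat(sprintf("  %-12s %d positive colors\n", cl, length(x$positive[[cl]])))
  invisible(x)
}

#' Read polygon annotations from a JSON file
#'
#' The file is a JSON array of objects
#' `{"image": <filename>, "label": <class>, "polygon": [[x, y], ...]}`
#' with 0-based pixel coordinates, origin top-left.
#'
#' @param path Path to the JSON annotation file.
#' @return List of [region_annotation] objects.
#' @export
read_annotations <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  lapply(recs, function(r) {
    poly <- do.call(rbind, lapply(r$polygon, as.numeric))
    region_annotation(r$image, r$label, poly)
  })
}

#' Write polygon annotations to a JSON file
#'
#' @param annotations List of [region_annotation] objects.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  recs <- lapply(annotations, function(a) list(
    image = a$image_id, label = a$label,
    polygon = lapply(seq_len(nrow(a$polygon)),
                     function(i) as.numeric(a$polygon[i, ]))))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Save / load a training table or palette as JSON
#'
#' Sparse JSON serialization so that a training run can be reloaded and
#' merged with later annotations, or applied to new image batches.
#'
#' @param x A `color_training_table` or `stain_palette`.
#' @param path File path.
#' @return `write_color_model()` returns the path invisibly;
#'   `read_color_model()` returns the reconstructed object.
#' @export
write_color_model <- function(x, path) {
  if (inherits(x, "color_training_table")) {
    obj <- list(type = "color_training_table", levels = x$levels,
                classes = as.list(x$classes), keys = x$keys,
                counts = as.data.frame(x$counts))
  } else if (inherits(x, "stain_palette")) {
    obj <- list(type = "stain_palette", levels = x$levels,
                threshold = x$threshold, classes = as.list(x$classes),
                positive = x$positive, unseen_policy = x$unseen_policy,
                observed_keys = x$observed_keys,
                observed_labels = x$observed_labels)
  } else stop("unsupported object", call. = FALSE)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_color_model
#' @export
read_color_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (identical(obj$type, "color_training_table")) {
    counts <- as.matrix(obj$counts)
    new_training_table(obj$levels, unlist(obj$classes), obj$keys, counts)
  } else if (identical(obj$type, "stain_palette")) {
    pos <- lapply(obj$positive, as.numeric)
    # a class with no colors deserializes as list(); normalize
    pos <- lapply(pos, function(p) if (length(p)) p else numeric(0))
    structure(list(levels = as.integer(obj$levels),
                   threshold = obj$threshold,
                   classes = unlist(obj$classes),
                   positive = pos[unlist(obj$classes)],
                   unseen_policy = obj$unseen_policy,
                   observed_keys = as.numeric(obj$observed_keys),
                   observed_labels = as.integer(obj$observed_labels)),
              class = "stain_palette")
  } else stop("unrecognized color-model file: ", path, call. = FALSE)
}
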