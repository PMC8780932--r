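#' Segmentation post-processing parameters
#'
#' Bundles the cleanup options applied after per-pixel classification:
#' slide-background exclusion (a pixel is blank slide when all three
#' channels are at least `background_min_channel`), connected-component
#' size thresholds, and an ordered list of morphological steps. The
#' default post-processing order is background exclusion, then
#' morphology, then size filtering, so that size thresholds act on the
#' final cleaned components.
#'
#' @param background_exclusion Logical; relabel near-white pixels as
#'   slide background.
#' @param background_min_channel Integer in `[0, 255]`; default 220.
#' @param min_component_area,max_component_area Component area bounds in
#'   pixels (`max_component_area = Inf` means unlimited).
#' @param morphology List of steps, each `list(op =, radius =)` with `op`
#'   one of `"open"`, `"close"`, `"fill_holes"`. The structuring element
#'   is `EBImage::makeBrush(2 * radius + 1, "disc")`.
#' @param connectivity Pixel connectivity for components: 8 (default) or 4.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(background_exclusion = FALSE,
                                background_min_channel = 220L,
                                min_component_area = 0L,
                                max_component_area = Inf,
                                morphology = list(),
                                connectivity = 8L) {
  if (background_min_channel < 0 || background_min_channel > 255)
    stop("`background_min_channel` must lie in [0, 255]", call. = FALSE)
  if (min_component_area > max_component_area)
    stop("`min_component_area` must not exceed `max_component_area`",
         call. = FALSE)
  if (!connectivity %in% c(4L, 8L))
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  for (st in morphology) {
    if (!st$op %in% c("open", "close", "fill_holes"))
      stop("unknown morphology op: ", st$op, call. = FALSE)
    if (!is.null(st$radius) && st$radius < 0)
      stop("morphology radius must be >= 0", call. = FALSE)
  }
  structure(list(background_exclusion = isTRUE(background_exclusion),
                 background_min_channel = as.integer(background_min_channel),
                 min_component_area = min_component_area,
                 max_component_area = max_component_area,
                 morphology = morphology,
                 connectivity = as.integer(connectivity)),
            class = "segmentation_params")
}

#' Classify every pixel of an image against a trained palette
#'
#' Each pixel's quantized color is looked up in the palette's positive
#' color lists; members are labeled with their class, non-members are
#' negative. Under `unseen_policy = "nearest"`, colors never seen in
#' training take the label of the nearest observed quantized color
#' (Euclidean distance over bin indices; ties resolve to negative).
#' Classification is strictly per-pixel and deterministic.
#'
#' @param image An [rgb_image].
#' @param palette A `stain_palette` from [derive_palette()].
#' @return A [label_mask] over the palette's classes.
#' @export
classify_pixels <- function(image, palette) {
  stopifnot(inherits(image, "rgb_image"), inherits(palette, "stain_palette"))
  keys <- image_keys(image, palette$levels)
  pos_keys <- unlist(palette$positive, use.names = FALSE)
  pos_class <- rep.int(seq_along(palette$classes),
                       lengths(palette$positive))
  hit <- match(keys, pos_keys)
  lab <- ifelse(is.na(hit), 0L, pos_class[hit])
  if (palette$unseen_policy == "nearest") {
    unseen <- is.na(match(keys, palette$observed_keys)) & lab == 0L
    if (any(unseen)) {
      uk <- unique(keys[unseen])
      lab_u <- nearest_observed_label(uk, palette)
      lab[unseen] <- lab_u[match(keys[unseen], uk)]
    }
  }
  d <- dim(image$pixels)
  label_mask(matrix(as.integer(lab), d[1], d[2]),
             classes = palette$classes, image_id = image$id)
}

# Nearest-observed-color label for unseen quantized colors. Ties in
# distance resolve to negative (label 0) when the tied labels disagree.
nearest_observed_label <- function(keys, palette) {
  q <- key_to_bins(keys, palette$levels)
  obs <- key_to_bins(palette$observed_keys, palette$levels)
  vapply(seq_len(nrow(q)), function(i) {
    d2 <- (obs[, 1] - q[i, 1])^2 + (obs[, 2] - q[i, 2])^2 +
      (obs[, 3] - q[i, 3])^2
    near <- which(d2 == min(d2))
    labs <- unique(palette$observed_labels[near])
    if (length(labs) == 1L) labs else 0L
  }, integer(1))
}

#' Relabel near-white slide background in a label mask
#'
#' Pixels whose three channels are all at least
#' `params$background_min_channel` are relabeled `background`, whatever
#' the palette said; all other labels are preserved. Returns the mask
#' unchanged when `params$background_exclusion` is off.
#'
#' @param image The source [rgb_image].
#' @param mask The [label_mask] from [classify_pixels()].
#' @param params A [segmentation_params].
#' @return The updated [label_mask].
#' @export
exclude_background <- function(image, mask, params) {
  stopifnot(inherits(mask, "label_mask"))
  if (!params$background_exclusion) return(mask)
  bg <- slide_background_mask(image, params$background_min_channel)
  v <- unclass(mask)
  v[bg] <- -1L
  label_mask(v, classes = attr(mask, "classes"),
             image_id = attr(mask, "image_id"))
}

slide_background_mask <- function(image, min_channel) {
  px <- image$pixels
  px[, , 1] >= min_channel & px[, , 2] >= min_channel & px[, , 3] >= min_channel
}

#' Label connected components of a binary mask
#'
#' @param mask Logical matrix.
#' @param connectivity 4 or 8.
#' @return Integer matrix of component labels (0 = off).
#' @export
label_components <- function(mask, connectivity = 8L) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  on <- which(mask)
  if (!length(on)) return(lab)
  id <- match(seq_len(h * w), on)  # node index per pixel, NA if off
  edges <- integer(0)
  add_edges <- function(di, dj) {
    i <- (on - 1L) %% h + 1L
    j <- (on - 1L) %/% h + 1L
    ok <- i + di >= 1L & i + di <= h & j + dj >= 1L & j + dj <= w
    from <- on[ok]
    to <- from + di + dj * h
    keep <- mask[to]
    rbind(id[from[keep]], id[to[keep]])
  }
  pairs <- list(add_edges(1L, 0L), add_edges(0L, 1L))
  if (connectivity == 8L)
    pairs <- c(pairs, list(add_edges(1L, 1L), add_edges(-1L, 1L)))
  g <- igraph::make_graph(edges = unlist(pairs), n = length(on),
                          directed = FALSE)
  comp <- igraph::components(g)$membership
  lab[on] <- as.integer(comp)
  lab
}

#' Remove connected components outside a size window
#'
#' Components (at `params$connectivity`) whose pixel area is below
#' `min_component_area` or above `max_component_area` are removed;
#' surviving pixels are unchanged, so positive area never increases.
#'
#' @param mask A [binary_mask].
#' @param params A [segmentation_params].
#' @return The filtered [binary_mask].
#' @export
filter_components <- function(mask, params) {
  if (params$min_component_area <= 1 && is.infinite(params$max_component_area))
    return(mask)
  lab <- label_components(mask, params$connectivity)
  if (max(lab) == 0L) return(mask)
  areas <- tabulate(lab)
  keep <- which(areas >= params$min_component_area &
                  areas <= params$max_component_area)
  out <- matrix(lab %in% keep & mask, nrow(mask), ncol(mask))
  binary_mask(out, image_id = attr(mask, "image_id"),
              class_name = attr(mask, "class_name"))
}

#' Apply morphological cleanup steps to a binary mask
#'
#' Steps run in the configured order. `open` and `close` use a disc
#' structuring element of the given radius (radius 0 is the identity);
#' `fill_holes` fills false regions not connected to the image border.
#' Out-of-image neighborhoods count as foreground during erosion and as
#' background during dilation, so features touching the image border are
#' not artificially eroded away.
#'
#' @param mask A [binary_mask].
#' @param params A [segmentation_params] whose `morphology` list drives
#'   the steps.
#' @return The processed [binary_mask].
#' @export
apply_morphology <- function(mask, params) {
  steps <- params$morphology
  if (!length(steps)) return(mask)
  img <- EBImage::Image(unclass(mask) * 1)
  for (st in steps) {
    r <- if (is.null(st$radius)) 1L else as.integer(st$radius)
    if (st$op == "fill_holes") {
      img <- EBImage::fillHull(img)
    } else if (r > 0L) {
      brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
      img <- switch(st$op,
                    open = EBImage::opening(img, brush),
                    close = EBImage::closing(img, brush))
    }
  }
  binary_mask(EBImage::imageData(img) > 0.5,
              image_id = attr(mask, "image_id"),
              class_name = attr(mask, "class_name"))
}

#' Full post-processing of a label mask
#'
#' Convenience wrapper applying, in order: background exclusion,
#' morphology, then component size filtering, each positive class
#' processed on its own binary mask and recombined (class masks are
#' disjoint by construction, so recombination is unambiguous).
#'
#' @param image Source [rgb_image].
#' @param mask [label_mask] from [classify_pixels()].
#' @param params A [segmentation_params].
#' @return The cleaned [label_mask].
#' @export
postprocess_labels <- function(image, mask, params) {
  mask <- exclude_background(image, mask, params)
  classes <- attr(mask, "classes")
  v <- unclass(mask)
  out <- v
  for (k in seq_along(classes)) {
    cm <- binary_mask(v == k, image_id = attr(mask, "image_id"),
                      class_name = classes[k])
    cm <- apply_morphology(cm, params)
    cm <- filter_components(cm, params)
    out[v == k & !cm] <- 0L          # pixels dropped from the class
    out[cm & out <= 0L & v != -1L] <- k  # pixels added by close/fill
    out[cm & v == -1L] <- -1L        # background exclusion wins
  }
  label_mask(out, classes = classes, image_id = attr(mask, "image_id"))
}

#' Baseline axis-aligned RGB box-threshold classifier
#'
#' The comparison baseline: a pixel is positive when each channel falls
#' inside its inclusive interval, i.e. the positive set is an
#' axis-aligned box in RGB space.
#'
#' @param image An [rgb_image].
#' @param r_range,g_range,b_range Length-2 inclusive channel intervals in
#'   `[0, 255]`.
#' @return A [binary_mask].
#' @export
threshold_baseline <- function(image, r_range, g_range, b_range) {
  for (rng in list(r_range, g_range, b_range)) {
    if (length(rng) != 2L || rng[1] > rng[2] || rng[1] < 0 || rng[2] > 255)
      stop("each channel range must be an interval within [0, 255]",
           call. = FALSE)
  }
  px <- image$pixels
  m <- px[, , 1] >= r_range[1] & px[, , 1] <= r_range[2] &
    px[, , 2] >= g_range[1] & px[, , 2] <= g_range[2] &
    px[, , 3] >= b_range[1] & px[, , 3] <= b_range[2]
  binary_mask(m, image_id = image$id, class_name = "box_threshold")
}

#' Grid-search the best RGB box threshold against labeled pixels
#'
#' Exhaustively searches axis-aligned boxes whose bounds lie on a uniform
#' grid (default step 8 per channel) for the box maximizing Youden's J
#' (true-positive rate minus false-positive rate) against the supplied
#' truth labels. Uses 3D cumulative counts so the search over all
#' `O((256/step)^6)` boxes reduces to nested range sweeps with a
#' maximum-subarray pass over the last channel.
#'
#' @param image An [rgb_image].
#' @param truth A [binary_mask] of the true positive pixels.
#' @param step Grid step in channel values (default 8).
#' @return List with `r_range`, `g_range`, `b_range` (inclusive, on the
#'   grid) and the achieved `j` on the training pixels.
#' @export
fit_box_threshold <- function(image, truth, step = 8L) {
  px <- pixel_matrix(image)
  pos <- as.vector(unclass(truth))
  nb <- as.integer(256 / step)
  bin <- floor(px / step) + 1L  # 1-based bin per channel
  # red varies fastest so the histogram array has dims (r, g, b)
  idx <- ((bin[, 3] - 1L) * nb + (bin[, 2] - 1L)) * nb + bin[, 1]
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0L || nn == 0L)
    stop("need both positive and negative truth pixels", call. = FALSE)
  hp <- tabulate(idx[pos], nbins = nb^3) / np
  hn <- tabulate(idx[!pos], nbins = nb^3) / nn
  q <- array(hp - hn, dim = c(nb, nb, nb))  # J contribution per bin
  # cumulative over the red axis for O(1) red-range slabs
  qc0 <- apply(q, c(2, 3), cumsum)          # dims: r, g, b
  qc <- array(0, dim = c(nb + 1L, nb, nb))
  qc[2:(nb + 1L), , ] <- qc0
  best <- -Inf; best_box <- NULL
  for (r1 in 1:nb) for (r2 in r1:nb) {
    slab <- qc[r2 + 1L, , ] - qc[r1, , ]    # g x b matrix
    cg <- rbind(0, apply(slab, 2, cumsum))  # (nb+1) x nb
    for (g1 in 1:nb) {
      rows <- cg[(g1 + 1L):(nb + 1L), , drop = FALSE] -
        matrix(cg[g1, ], nrow = nb - g1 + 1L, ncol = nb, byrow = TRUE)
      cb <- cbind(0, t(apply(rows, 1, cumsum)))  # cumsum over b per g2
      for (g2i in seq_len(nrow(rows))) {
        v <- cb[g2i, ]
        b2 <- which.max(v - cummin(c(Inf, v[-length(v)])))
        b1 <- which.min(v[seq_len(b2 - 1L)])
        val <- v[b2] - v[b1]
        if (val > best) {
          best <- val
          best_box <- c(r1, r2, g1, g1 + g2i - 1L, b1, b2 - 1L)
        }
      }
    }
  }
  to_range <- function(lo, hi) c((lo - 1L) * step, hi * step - 1L)
  list(r_range = to_range(best_box[1], best_box[2]),
       g_range = to_range(best_box[3], best_box[4]),
       b_range = to_range(best_box[5], best_box[6]),
       j = best)
}

#' Alpha-blend class overlays onto an image
#'
#' Renders the classification for visual review: the output equals the
#' input wherever the mask is negative or background, and an
#' alpha-blended class color elsewhere. The source image is untouched.
#'
#' @param image An [rgb_image].
#' @param mask A [label_mask].
#' @param colors Named list/vector of `c(r, g, b)` overlay colors, one
#'   per positive class.
#' @param opacity Blend weight in `[0, 1]`; 1 paints the pure class color.
#' @return A new [rgb_image].
#' @export
render_overlay <- function(image, mask, colors, opacity = 0.5) {
  stopifnot(inherits(image, "rgb_image"), inherits(mask, "label_mask"))
  classes <- attr(mask, "classes")
  missing_cols <- setdiff(classes, names(colors))
  if (length(missing_cols))
    stop("no overlay color for class(es): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  px <- image$pixels
  v <- unclass(mask)
  for (k in seq_along(classes)) {
    sel <- v == k
    if (!any(sel)) next
    col <- colors[[classes[k]]]
    for (ch in 1:3) {
      plane <- px[, , ch]
      plane[sel] <- as.integer(round((1 - opacity) * plane[sel] +
                                       opacity * col[ch]))
      px[, , ch] <- plane
    }
  }
  rgb_image(px, id = paste0(image$id, "_overlay"))
}

#' Partition images into continuous and edge fields
#'
#' An automated stand-in for manual sorting of tiled fields of view: an
#' image is flagged `edge` when its slide-background pixel fraction
#' (near-white test from `params`) exceeds `max_background_fraction`,
#' `continuous` otherwise. Off by default in the pipeline; enabling it
#' logs the excluded files for review.
#'
#' @param images List of [rgb_image] objects.
#' @param params A [segmentation_params] (supplies the background test).
#' @param max_background_fraction Cutoff in `[0, 1]`.
#' @return List with elements `continuous` and `edge`, each a character
#'   vector of image ids, plus `background_fraction` named per image.
#' @export
flag_edge_images <- function(images, params, max_background_fraction = 0.25) {
  if (inherits(images, "rgb_image")) images <- list(images)
  frac <- vapply(images, function(im)
    mean(slide_background_mask(im, params$background_min_channel)),
    numeric(1))
  ids <- vapply(images, function(im) im$id, "")
  names(frac) <- ids
  is_edge <- frac > max_background_fraction
  list(continuous = ids[!is_edge], edge = ids[is_edge],
       background_fraction = frac)
}
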