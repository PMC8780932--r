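#' RGB raster image container
#'
#' Wraps an 8-bit RGB raster as an integer array together with a stable
#' identifier. All classification and quantification functions in the
#' package operate on this container; source pixels are never modified
#' by any downstream operation.
#'
#' @param pixels Integer array of dimension `H x W x 3`, channel values in
#'   `[0, 255]` (red, green, blue).
#' @param id Character identifier, typically the source file name.
#' @return An object of class `rgb_image` with fields `pixels` and `id`.
#' @export
rgb_image <- function(pixels, id = "image") {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an H x W x 3 array", call. = FALSE)
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop("image must have at least one row and one column", call. = FALSE)
  storage.mode(pixels) <- "integer"
  if (anyNA(pixels) || min(pixels) < 0L || max(pixels) > 255L)
    stop("channel values must be integers in [0, 255]", call. = FALSE)
  structure(list(pixels = pixels, id = as.character(id)),
            class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<rgb_image '%s': %d x %d, 8-bit RGB>\n", x$id, d[1], d[2]))
  invisible(x)
}

#' @export
dim.rgb_image <- function(x) dim(x$pixels)[1:2]

#' Read an RGB image from file
#'
#' Reads PNG, TIFF or JPEG files into an [rgb_image]. Images are forced to
#' 8-bit RGB: grayscale inputs are replicated across channels, an alpha
#' channel is dropped, and non-8-bit data are rescaled with a warning.
#' Multi-page TIFF files are rejected.
#'
#' @param path Path to a PNG, TIFF or JPEG file.
#' @param id Identifier to store; defaults to the file name.
#' @return An [rgb_image].
#' @export
read_image <- function(path, id = basename(path)) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  img <- EBImage::readImage(path)
  if (EBImage::numberOfFrames(img, type = "render") > 1L)
    stop("multi-page image not supported: ", path, call. = FALSE)
  a <- EBImage::imageData(img)  # numeric in [0,1], dims (x, y[, channels])
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  if (dim(a)[3] < 3L) a <- array(rep(a[, , 1L], 3L), dim = c(dim(a)[1:2], 3L))
  if (max(a) > 1 + 1e-9) {
    warning("non 8-bit image rescaled to [0, 255]: ", path, call. = FALSE)
    a <- a / max(a)
  }
  # EBImage stores x (width) as the first dimension; transpose to H x W
  px <- array(0L, dim = c(dim(a)[2], dim(a)[1], 3L))
  for (k in 1:3) px[, , k] <- as.integer(round(t(a[, , k]) * 255))
  rgb_image(px, id = id)
}

#' Write an RGB image to a PNG file
#'
#' @param image An [rgb_image].
#' @param path Output path (`.png`).
#' @return The path, invisibly.
#' @export
write_image_png <- function(image, path) {
  stopifnot(inherits(image, "rgb_image"))
  d <- dim(image$pixels)
  a <- array(0, dim = c(d[2], d[1], 3L))
  for (k in 1:3) a[, , k] <- t(image$pixels[, , k]) / 255
  EBImage::writeImage(EBImage::Image(a, colormode = "Color"), path)
  invisible(path)
}

#' Construct a binary mask
#'
#' A binary mask is a logical `H x W` matrix carrying the source image id
#' and the class name it refers to as attributes.
#'
#' @param values Logical matrix.
#' @param image_id Source image identifier.
#' @param class_name Class the mask refers to.
#' @return A logical matrix of class `binary_mask`.
#' @export
binary_mask <- function(values, image_id = "image", class_name = "positive") {
  if (!is.matrix(values)) stop("`values` must be a matrix", call. = FALSE)
  storage.mode(values) <- "logical"
  values[is.na(values)] <- FALSE
  structure(values, image_id = image_id, class_name = class_name,
            class = c("binary_mask", "matrix", "array"))
}

#' Read a reference mask from an image file
#'
#' Any nonzero pixel is treated as positive (in multichannel files, a pixel
#' is positive if any channel is nonzero).
#'
#' @param path Path to a single-channel (or RGB) mask image.
#' @param class_name Class name to attach.
#' @return A [binary_mask].
#' @export
read_mask <- function(path, class_name = "positive") {
  a <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(a)) == 3L) a <- apply(a, c(1, 2), max)
  binary_mask(t(a) > 0, image_id = basename(path), class_name = class_name)
}

#' Write a binary mask as a 0/255 PNG file
#'
#' @param mask A [binary_mask] (or logical matrix).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  EBImage::writeImage(EBImage::Image(t(mask * 1)), path)
  invisible(path)
}

#' Construct a label mask
#'
#' Integer `H x W` matrix coding one label per pixel: `0` = negative,
#' `-1` = slide background, `k > 0` = the k-th declared positive class.
#'
#' @param values Integer matrix of codes.
#' @param classes Character vector of positive class names.
#' @param image_id Source image identifier.
#' @return An integer matrix of class `label_mask`.
#' @export
label_mask <- function(values, classes, image_id = "image") {
  storage.mode(values) <- "integer"
  if (length(classes) < 1L) stop("at least one positive class required", call. = FALSE)
  bad <- values > length(classes) | values < -1L
  if (any(bad)) stop("label codes outside declared classes", call. = FALSE)
  structure(values, classes = as.character(classes), image_id = image_id,
            class = c("label_mask", "matrix", "array"))
}

#' Extract one class from a label mask as a binary mask
#'
#' @param labels A [label_mask].
#' @param class_name One of the mask's positive class names, or
#'   `"negative"` / `"background"`.
#' @return A [binary_mask] for that class.
#' @export
class_mask <- function(labels, class_name) {
  stopifnot(inherits(labels, "label_mask"))
  classes <- attr(labels, "classes")
  code <- switch(class_name,
                 negative = 0L,
                 background = -1L,
                 {
                   k <- match(class_name, classes)
                   if (is.na(k)) stop("unknown class: ", class_name, call. = FALSE)
                   k
                 })
  binary_mask(unclass(labels) == code,
              image_id = attr(labels, "image_id"), class_name = class_name)
}
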