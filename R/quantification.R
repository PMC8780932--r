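#' Percent positive area of a mask
#'
#' The core readout: `100 * positive pixels / denominator pixels`. The
#' denominator is either every pixel of the field (`whole_image`, the
#' default) or only tissue pixels (`tissue_only`: all pixels minus the
#' supplied slide-background mask). Counts are integer; only the final
#' division is floating point.
#'
#' @param mask A [binary_mask] of positive pixels.
#' @param denominator_mode `"whole_image"` or `"tissue_only"`.
#' @param background A [binary_mask] of slide-background pixels, required
#'   for `tissue_only`.
#' @return Percentage in `[0, 100]`.
#' @export
percent_positive_area <- function(mask,
                                  denominator_mode = c("whole_image",
                                                       "tissue_only"),
                                  background = NULL) {
  denominator_mode <- match.arg(denominator_mode)
  pos <- sum(mask)
  if (denominator_mode == "whole_image") {
    denom <- length(mask)
  } else {
    if (is.null(background))
      stop("tissue_only mode requires a background mask", call. = FALSE)
    denom <- sum(!background)
    if (denom == 0L)
      stop("undefined denominator: no tissue pixels outside background",
           call. = FALSE)
  }
  100 * pos / denom
}

#' Area ratio between two class masks
#'
#' Pixel count of `mask_a` divided by pixel count of `mask_b` (e.g. the
#' brown TUNEL-positive to blue TUNEL-negative nuclear area ratio). An
#' empty `mask_b` makes the ratio undefined; it is reported as `NA`
#' (never silently 0) so batch summaries can count missing values.
#'
#' @param mask_a,mask_b [binary_mask]s from the same image.
#' @return The ratio, or `NA_real_` with a warning when `mask_b` is empty.
#' @export
class_area_ratio <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b)))
    stop("masks must come from the same image (shape mismatch)", call. = FALSE)
  nb <- sum(mask_b)
  if (nb == 0L) {
    warning("undefined class-area ratio: denominator mask is empty",
            call. = FALSE)
    return(NA_real_)
  }
  sum(mask_a) / nb
}

#' Per-image quantification report
#'
#' One row per positive class with percent positive area, pixel count,
#' connected-component count and component-area order statistics, plus
#' the image's tissue fraction (share of pixels not labeled slide
#' background) and the denominator convention used — recorded so results
#' are never ambiguous.
#'
#' @param labels A cleaned [label_mask] (after [postprocess_labels()]).
#' @param denominator_mode `"whole_image"` (default) or `"tissue_only"`.
#' @param connectivity Component connectivity for the per-class counts.
#' @return A `data.frame` of class `image_report`, one row per class:
#'   `image_id`, `class`, `percent_positive_area`, `positive_pixel_count`,
#'   `component_count`, `component_area_min` / `_median` / `_max`,
#'   `denominator_mode`, `tissue_fraction`.
#' @export
image_report <- function(labels,
                         denominator_mode = c("whole_image", "tissue_only"),
                         connectivity = 8L) {
  stopifnot(inherits(labels, "label_mask"))
  denominator_mode <- match.arg(denominator_mode)
  classes <- attr(labels, "classes")
  v <- unclass(labels)
  bg <- binary_mask(v == -1L)
  tissue_fraction <- 1 - mean(bg)
  rows <- lapply(seq_along(classes), function(k) {
    cm <- binary_mask(v == k)
    lab <- label_components(cm, connectivity)
    areas <- if (max(lab) > 0L) tabulate(lab) else integer(0)
    pct <- if (denominator_mode == "tissue_only")
      percent_positive_area(cm, "tissue_only", background = bg)
    else percent_positive_area(cm, "whole_image")
    data.frame(image_id = attr(labels, "image_id"),
               class = classes[k],
               percent_positive_area = pct,
               positive_pixel_count = sum(cm),
               component_count = length(areas),
               component_area_min = if (length(areas)) min(areas) else NA_integer_,
               component_area_median = if (length(areas)) stats::median(areas) else NA_real_,
               component_area_max = if (length(areas)) max(areas) else NA_integer_,
               denominator_mode = denominator_mode,
               tissue_fraction = tissue_fraction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("image_report", "data.frame")
  out
}

#' Summarize per-image reports over a batch
#'
#' Per-class order statistics over the per-image percent positive areas:
#' median (midpoint-interpolated for even n, i.e. `stats::median()`),
#' interquartile range, minimum, maximum and image count. Undefined
#' values (`NA`) are excluded from the statistics and counted in
#' `n_missing`. The per-image values remain available in the input for
#' external plotting and statistics.
#'
#' @param reports One or more [image_report()] data frames (a list or a
#'   single row-bound data frame).
#' @return A `data.frame`, one row per class: `class`, `n_images`,
#'   `n_missing`, `median`, `iqr`, `q25`, `q75`, `min`, `max`.
#' @export
summarize_batch <- function(reports) {
  if (is.data.frame(reports)) reports <- list(reports)
  if (!length(reports)) stop("no reports to summarize", call. = FALSE)
  df <- do.call(rbind, lapply(reports, as.data.frame))
  if (!nrow(df)) stop("no reports to summarize", call. = FALSE)
  out <- lapply(split(df, df$class), function(d) {
    x <- d$percent_positive_area
    miss <- sum(is.na(x)); x <- x[!is.na(x)]
    qs <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
    data.frame(class = d$class[1], n_images = nrow(d), n_missing = miss,
               median = stats::median(x), iqr = qs[2] - qs[1],
               q25 = qs[1], q75 = qs[2], min = min(x), max = max(x),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write per-image reports or batch summaries as CSV
#'
#' Plain UTF-8, header row, '.' decimal separator; one row per
#' (image, class). `NA` values are written as empty fields.
#'
#' @param x A data frame ([image_report()] rows or [summarize_batch()]
#'   output).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_report_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  invisible(path)
}
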