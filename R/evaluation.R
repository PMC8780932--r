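#' Consensus reference mask from multiple annotators
#'
#' Builds the consensus hand-traced standard: a pixel is positive only
#' when every annotator marked it (logical AND / intersection). A
#' majority-vote rule is available as an explicit non-default option for
#' larger annotator panels.
#'
#' @param masks List of two or more [binary_mask]s of identical shape.
#' @param rule `"intersection"` (default) or `"majority"` (strictly more
#'   than half of the annotators).
#' @return The consensus [binary_mask].
#' @export
consensus_standard <- function(masks, rule = c("intersection", "majority")) {
  rule <- match.arg(rule)
  if (length(masks) < 2L)
    stop("consensus needs at least 2 masks", call. = FALSE)
  d <- dim(masks[[1]])
  for (m in masks)
    if (!identical(dim(m), d))
      stop("consensus masks must share one shape", call. = FALSE)
  votes <- Reduce(`+`, lapply(masks, function(m) unclass(m) * 1L))
  out <- if (rule == "intersection") votes == length(masks)
  else votes > length(masks) / 2
  binary_mask(out, image_id = attr(masks[[1]], "image_id"),
              class_name = attr(masks[[1]], "class_name"))
}

#' Pixel confusion matrix of a predicted mask against a reference
#'
#' Tallies every evaluated pixel into exactly one of four outcomes:
#' TP (positive in both), FP (predicted only), FN (reference only),
#' TN (neither). An optional evaluation region restricts which pixels
#' are counted (e.g. tissue-only evaluation).
#'
#' @param predicted,reference [binary_mask]s of identical shape.
#' @param evaluate_region Optional [binary_mask]; only `TRUE` pixels are
#'   tallied.
#' @return A `confusion_counts` list with integer fields `tp`, `fp`,
#'   `fn`, `tn`.
#' @export
confusion_matrix <- function(predicted, reference, evaluate_region = NULL) {
  if (!identical(dim(predicted), dim(reference)))
    stop("predicted and reference masks differ in shape", call. = FALSE)
  p <- as.vector(unclass(predicted))
  r <- as.vector(unclass(reference))
  if (!is.null(evaluate_region)) {
    if (!identical(dim(evaluate_region), dim(predicted)))
      stop("evaluation region differs in shape", call. = FALSE)
    keep <- as.vector(unclass(evaluate_region))
    p <- p[keep]; r <- r[keep]
  }
  confusion_counts(tp = sum(p & r), fp = sum(p & !r),
                   fn = sum(!p & r), tn = sum(!p & !r))
}

#' Construct confusion counts directly
#'
#' @param tp,fp,fn,tn Non-negative integer pixel counts.
#' @return A `confusion_counts` object.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (anyNA(counts) || any(counts < 0))
    stop("confusion counts must be non-negative", call. = FALSE)
  structure(as.list(counts), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts: TP=%d FP=%d FN=%d TN=%d>\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Youden's J statistic (informedness)
#'
#' `J = TP/(TP+FN) + TN/(TN+FP) - 1 = sensitivity + specificity - 1`,
#' the probability that the classifier makes an informed decision rather
#' than a random guess. Undefined (returned as `NA`) when either the
#' positive or the negative reference class is empty.
#'
#' @param c A `confusion_counts` object.
#' @return J in `[-1, 1]`, or `NA_real_` when undefined.
#' @export
youden_j <- function(c) {
  if ((c$tp + c$fn) == 0 || (c$tn + c$fp) == 0) return(NA_real_)
  c$tp / (c$tp + c$fn) + c$tn / (c$tn + c$fp) - 1
}

#' F-score
#'
#' `F = 2 TP / (2 TP + FP + FN)`, the harmonic mean of precision and
#' sensitivity. Undefined (`NA`) when no positives exist anywhere
#' (`TP = FP = FN = 0`).
#'
#' @param c A `confusion_counts` object.
#' @return F in `[0, 1]`, or `NA_real_` when undefined.
#' @export
f_score <- function(c) {
  denom <- 2 * c$tp + c$fp + c$fn
  if (denom == 0) return(NA_real_)
  2 * c$tp / denom
}

#' Matthews correlation coefficient
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, a
#' balanced correlation using all four confusion-matrix cells, computed
#' in double precision to avoid integer overflow. When any factor of the
#' denominator is zero (e.g. a constant prediction) the coefficient is
#' returned as 0 — the standard chance-level convention — with the
#' `degenerate` attribute set.
#'
#' @param c A `confusion_counts` object.
#' @return MCC in `[-1, 1]`; attribute `degenerate` is `TRUE` when the
#'   zero-denominator convention was applied.
#' @export
mcc <- function(c) {
  tp <- as.numeric(c$tp); fp <- as.numeric(c$fp)
  fn <- as.numeric(c$fn); tn <- as.numeric(c$tn)
  f1 <- tp + fp; f2 <- tp + fn; f3 <- tn + fp; f4 <- tn + fn
  if (f1 == 0 || f2 == 0 || f3 == 0 || f4 == 0)
    return(structure(0, degenerate = TRUE))
  structure((tp * tn - fp * fn) / sqrt(f1 * f2 * f3 * f4),
            degenerate = FALSE)
}

#' All agreement metrics from one confusion matrix
#'
#' @param c A `confusion_counts` object.
#' @return A one-row `data.frame` with the four counts, sensitivity,
#'   specificity, precision, accuracy, Youden's J, F-score and MCC
#'   (undefined metrics as `NA`; MCC degeneracy flagged in
#'   `mcc_degenerate`).
#' @export
metric_set <- function(c) {
  sens <- if ((c$tp + c$fn) > 0) c$tp / (c$tp + c$fn) else NA_real_
  spec <- if ((c$tn + c$fp) > 0) c$tn / (c$tn + c$fp) else NA_real_
  prec <- if ((c$tp + c$fp) > 0) c$tp / (c$tp + c$fp) else NA_real_
  total <- c$tp + c$fp + c$fn + c$tn
  acc <- if (total > 0) (c$tp + c$tn) / total else NA_real_
  m <- mcc(c)
  data.frame(tp = c$tp, fp = c$fp, fn = c$fn, tn = c$tn,
             sensitivity = sens, specificity = spec, precision = prec,
             accuracy = acc, youden_j = youden_j(c), f_score = f_score(c),
             mcc = as.numeric(m), mcc_degenerate = attr(m, "degenerate"),
             stringsAsFactors = FALSE)
}

#' Evaluate predicted masks against references over an image set
#'
#' Pairs predicted and reference masks by image id, computes one metric
#' row per image, and appends a pooled row (`image_id = "pooled"`) whose
#' metrics are computed from the entrywise-summed confusion counts
#' (micro-averaging) — not the mean of per-image metrics.
#'
#' @param predicted,reference Named lists of [binary_mask]s; names (or
#'   `image_id` attributes) pair them.
#' @param evaluate_region Optional named list of region masks.
#' @return A `data.frame`: one row per image plus the pooled row, columns
#'   as in [metric_set()].
#' @export
evaluate_method <- function(predicted, reference, evaluate_region = NULL) {
  ids_of <- function(ms) {
    nm <- names(ms)
    if (is.null(nm))
      nm <- vapply(ms, function(m) attr(m, "image_id"), "")
    nm
  }
  pid <- ids_of(predicted); rid <- ids_of(reference)
  unmatched <- c(setdiff(pid, rid), setdiff(rid, pid))
  if (length(unmatched))
    stop("unmatched image id(s): ", paste(unique(unmatched), collapse = ", "),
         call. = FALSE)
  rows <- list(); pooled <- confusion_counts(0, 0, 0, 0)
  for (i in seq_along(pid)) {
    id <- pid[i]
    reg <- if (!is.null(evaluate_region)) evaluate_region[[id]] else NULL
    cc <- confusion_matrix(predicted[[i]], reference[[match(id, rid)]], reg)
    pooled <- confusion_counts(pooled$tp + cc$tp, pooled$fp + cc$fp,
                               pooled$fn + cc$fn, pooled$tn + cc$tn)
    rows[[i]] <- cbind(image_id = id, metric_set(cc))
  }
  out <- rbind(do.call(rbind, rows),
               cbind(image_id = "pooled", metric_set(pooled)))
  rownames(out) <- NULL
  out
}
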