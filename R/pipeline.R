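#' Resolve a run configuration
#'
#' Collects every setting of the batch pipeline, applying documented
#' defaults; the effective (fully resolved) configuration is written as
#' JSON next to each run's outputs so results are reproducible. Accepts
#' a named list (e.g. parsed from a YAML/JSON file) plus overrides.
#'
#' @param config Named list of settings (optional).
#' @param ... Individual overrides taking precedence over `config`.
#' @return A `run_config` list with all defaults resolved.
#' @export
run_config <- function(config = list(), ...) {
  defaults <- list(
    input = NULL,                 # directory or character vector of files
    pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
    palette = NULL,               # palette JSON path or stain_palette
    levels = 64L,
    threshold = 0.5,
    unseen_policy = "negative",
    background_exclusion = FALSE,
    background_min_channel = 220L,
    min_component_area = 0L,
    max_component_area = Inf,
    morphology = list(),
    connectivity = 8L,
    denominator_mode = "whole_image",
    output_dir = "stainpal_out",
    overlay = FALSE,
    overlay_colors = NULL,        # named list of c(r, g, b); auto if NULL
    overlay_opacity = 0.5,
    edge_filter = FALSE,
    edge_max_background_fraction = 0.25,
    log_level = "info")
  over <- list(...)
  for (nm in names(config)) defaults[[nm]] <- config[[nm]]
  for (nm in names(over)) defaults[[nm]] <- over[[nm]]
  structure(defaults, class = "run_config")
}

#' Read a run configuration file (YAML or JSON)
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file.
#' @return A `run_config` with defaults resolved.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  run_config(cfg)
}

write_effective_config <- function(config, out_dir) {
  cfg <- unclass(config)
  cfg$max_component_area <- if (is.infinite(cfg$max_component_area))
    "unlimited" else cfg$max_component_area
  jsonlite::write_json(cfg, file.path(out_dir, "effective_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

params_from_config <- function(config) {
  segmentation_params(
    background_exclusion = config$background_exclusion,
    background_min_channel = config$background_min_channel,
    min_component_area = config$min_component_area,
    max_component_area = config$max_component_area,
    morphology = config$morphology,
    connectivity = config$connectivity)
}

log_msg <- function(config, ...) {
  if (!identical(config$log_level, "quiet"))
    message(sprintf(...))
}

#' Train a palette from annotation files (pipeline command)
#'
#' Reads polygon annotations, loads the referenced training images,
#' accumulates the color map, optionally merges a previously saved
#' training table (the re-training second pass), derives the palette and
#' writes both as JSON.
#'
#' @param annotations Path to an annotation JSON file, or a list of
#'   [region_annotation]s.
#' @param image_dir Directory holding the referenced training images
#'   (ignored for entries given as loaded [rgb_image]s in `images`).
#' @param out Output path for the palette JSON; the training table is
#'   written next to it with suffix `_table.json`.
#' @param config A [run_config()] (supplies `levels`, `threshold`,
#'   `unseen_policy`).
#' @param merge_with Optional path to a previously written training
#'   table to merge before deriving the palette.
#' @param images Optional pre-loaded list of [rgb_image]s (bypasses
#'   `image_dir`).
#' @return List with `table`, `palette`, and the written `paths`.
#' @export
cmd_train <- function(annotations, image_dir = ".", out = "palette.json",
                      config = run_config(), merge_with = NULL,
                      images = NULL) {
  if (is.character(annotations)) annotations <- read_annotations(annotations)
  if (is.null(images)) {
    ids <- unique(vapply(annotations, function(a) a$image_id, ""))
    images <- lapply(ids, function(id) {
      # annotation ids may or may not carry the image file extension
      cand <- file.path(image_dir,
                        c(id, paste0(id, c(".png", ".tif", ".tiff",
                                           ".jpg", ".jpeg"))))
      p <- cand[file.exists(cand)][1]
      if (is.na(p))
        stop("annotation references a missing image file: ",
             file.path(image_dir, id), call. = FALSE)
      read_image(p, id = id)
    })
  }
  table <- accumulate_training(images, annotations, levels = config$levels)
  if (!is.null(merge_with)) {
    prev <- if (is.character(merge_with)) read_color_model(merge_with)
    else merge_with
    table <- merge_training(prev, table)
  }
  palette <- derive_palette(table, threshold = config$threshold,
                            unseen_policy = config$unseen_policy)
  table_path <- sub("\\.json$", "_table.json", out)
  write_color_model(table, table_path)
  write_color_model(palette, out)
  for (cl in colnames(table$counts))
    log_msg(config, "trained %-12s %d pixels, %d positive colors",
            cl, sum(table$counts[, cl]),
            if (cl == "negative") 0L else length(palette$positive[[cl]]))
  list(table = table, palette = palette, paths = c(out, table_path))
}

#' Batch-classify an image set (pipeline command)
#'
#' Runs every input image through the palette classifier and the
#' post-processing chain, writes per-class masks (0/255 PNG), optional
#' overlays, a per-image CSV, a batch summary CSV and the effective
#' config. Unreadable files are logged and skipped rather than aborting
#' the batch.
#'
#' @param config A [run_config()]; `input` and `palette` must be set.
#' @param images Optional pre-loaded list of [rgb_image]s (bypasses
#'   `input`).
#' @return List with `reports` (row-bound [image_report()]s), `summary`
#'   ([summarize_batch()] output), `failed` (character vector of failed
#'   inputs), and `n_processed`.
#' @export
cmd_run <- function(config, images = NULL) {
  palette <- if (inherits(config$palette, "stain_palette")) config$palette
  else if (is.character(config$palette)) read_color_model(config$palette)
  else stop("config$palette must be a palette or a palette file",
            call. = FALSE)
  files <- NULL
  if (is.null(images)) {
    files <- if (length(config$input) == 1L && dir.exists(config$input))
      list.files(config$input, pattern = config$pattern, full.names = TRUE)
    else config$input
    if (!length(files)) stop("no input images matched", call. = FALSE)
  }
  params <- params_from_config(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  write_effective_config(config, config$output_dir)
  n <- if (is.null(images)) length(files) else length(images)
  reports <- list(); failed <- character(0)
  edge_skipped <- character(0)
  for (i in seq_len(n)) {
    res <- tryCatch({
      img <- if (is.null(images)) read_image(files[i]) else images[[i]]
      if (config$edge_filter) {
        part <- flag_edge_images(list(img), params,
                                 config$edge_max_background_fraction)
        if (img$id %in% part$edge) {
          log_msg(config, "edge image excluded: %s (background %.1f%%)",
                  img$id, 100 * part$background_fraction[[img$id]])
          edge_skipped <- c(edge_skipped, img$id)
          return_null <- TRUE
        } else return_null <- FALSE
      } else return_null <- FALSE
      if (!return_null) {
        labels <- classify_pixels(img, palette)
        labels <- postprocess_labels(img, labels, params)
        stem <- tools::file_path_sans_ext(basename(img$id))
        for (cl in palette$classes)
          write_mask_png(class_mask(labels, cl),
                         file.path(config$output_dir,
                                   sprintf("%s_mask_%s.png", stem, cl)))
        if (isTRUE(config$overlay)) {
          cols <- config$overlay_colors
          if (is.null(cols)) {
            cols <- lapply(seq_along(palette$classes), function(k)
              c(c(255, 0, 255), c(0, 255, 255), c(255, 255, 0))[
                ((k - 1) %% 3) * 3 + 1:3])
            names(cols) <- palette$classes
          }
          ov <- render_overlay(img, labels, cols, config$overlay_opacity)
          write_image_png(ov, file.path(config$output_dir,
                                        sprintf("%s_overlay.png", stem)))
        }
        image_report(labels, denominator_mode = config$denominator_mode,
                     connectivity = config$connectivity)
      } else NULL
    }, error = function(e) {
      log_msg(config, "FAILED %s: %s",
              if (is.null(images)) files[i] else images[[i]]$id,
              conditionMessage(e))
      structure(character(0), failed = TRUE)
    })
    if (is.data.frame(res)) reports[[length(reports) + 1L]] <- res
    else if (!is.null(attr(res, "failed")))
      failed <- c(failed, if (is.null(images)) files[i] else images[[i]]$id)
  }
  if (!length(reports))
    stop("no image processed successfully", call. = FALSE)
  all_reports <- do.call(rbind, reports)
  summary <- summarize_batch(all_reports)
  write_report_csv(all_reports, file.path(config$output_dir,
                                          "per_image_reports.csv"))
  write_report_csv(summary, file.path(config$output_dir,
                                      "batch_summary.csv"))
  log_msg(config, "batch done: %d processed, %d failed, %d edge-excluded",
          length(reports), length(failed), length(edge_skipped))
  list(reports = all_reports, summary = summary, failed = failed,
       edge_skipped = edge_skipped, n_processed = length(reports))
}

#' Evaluate predicted masks against reference tracings (pipeline command)
#'
#' Pairs predicted mask files with reference mask files by file name.
#' When several reference directories are given (multiple annotators),
#' the consensus standard (intersection) is built per image first.
#' Writes per-image and pooled metrics as CSV.
#'
#' @param predicted_dir Directory of predicted mask images.
#' @param reference_dirs Character vector of one or more reference mask
#'   directories.
#' @param out CSV output path.
#' @param pattern File pattern for mask files.
#' @param consensus_rule Passed to [consensus_standard()].
#' @return The metrics `data.frame`, invisibly written to `out`.
#' @export
cmd_evaluate <- function(predicted_dir, reference_dirs,
                         out = "metrics.csv",
                         pattern = "\\.(png|tif|tiff)$",
                         consensus_rule = "intersection") {
  pf <- list.files(predicted_dir, pattern = pattern)
  rf <- list.files(reference_dirs[1], pattern = pattern)
  unpaired <- c(setdiff(pf, rf), setdiff(rf, pf))
  if (length(unpaired))
    stop("unpairable mask files: ", paste(unpaired, collapse = ", "),
         call. = FALSE)
  if (!length(pf)) stop("no mask files found", call. = FALSE)
  predicted <- lapply(pf, function(f)
    read_mask(file.path(predicted_dir, f)))
  names(predicted) <- pf
  reference <- lapply(pf, function(f) {
    refs <- lapply(reference_dirs, function(d) {
      p <- file.path(d, f)
      if (!file.exists(p))
        stop("reference mask missing from ", d, ": ", f, call. = FALSE)
      read_mask(p)
    })
    if (length(refs) > 1L) consensus_standard(refs, rule = consensus_rule)
    else refs[[1]]
  })
  names(reference) <- pf
  metrics <- evaluate_method(predicted, reference)
  write_report_csv(metrics, out)
  invisible(metrics)
}

#' Generate a synthetic fixture set (pipeline command)
#'
#' Materializes a synthetic spec — a preset name, a YAML/JSON spec file,
#' or a [synthetic_spec] — as PNG images, truth masks, training
#' annotations, metadata and a hashed manifest.
#'
#' @param spec Preset name (see [synthetic_preset()]), path to a
#'   YAML/JSON spec file, or a [synthetic_spec].
#' @param out_dir Output directory.
#' @param seed RNG seed.
#' @param with_training Also write a training pair and its annotations.
#' @return Paths of written files, invisibly.
#' @export
cmd_simulate <- function(spec, out_dir = "fixtures", seed = 1L,
                         with_training = TRUE) {
  if (is.character(spec) && length(spec) == 1L) {
    if (file.exists(spec)) {
      ext <- tolower(tools::file_ext(spec))
      raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(spec)
      else jsonlite::fromJSON(spec, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
      raw$classes <- lapply(raw$classes, function(cl) {
        if (!is.null(cl$color_model$color))
          cl$color_model$color <- as.numeric(cl$color_model$color)
        if (!is.null(cl$size_range)) cl$size_range <- as.numeric(cl$size_range)
        cl
      })
      spec <- do.call(synthetic_spec, raw)
    } else {
      spec <- synthetic_preset(spec, seed = seed)
    }
  }
  stopifnot(inherits(spec, "synthetic_spec"))
  fixture <- generate_synthetic(spec, seed = seed)
  annotations <- NULL
  extra <- character(0)
  if (with_training) {
    tp <- generate_training_pair(spec, seed = seed)
    annotations <- tp$annotations
    for (fx in tp$fixtures) extra <- c(extra, write_fixture_set(fx, out_dir))
  }
  paths <- write_fixture_set(fixture, out_dir, annotations = annotations)
  invisible(c(paths, extra))
}
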