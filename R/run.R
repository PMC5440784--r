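#' Extract variance features from image files to a CSV table
#'
#' End-to-end pipeline: each readable image is loaded, preprocessed, run
#' through the backbone, and its 45 variance features written as one CSV
#' row together with `image_id`, `layer` and a hash of the resolved
#' configuration. Unreadable files are skipped with a warning and counted
#' in the returned summary rather than aborting the run.
#'
#' @param paths Character vector of image files (PNG/JPEG/TIFF).
#' @param out Output CSV path, or `NULL` to only return the table.
#' @param cfg A [backbone_config()].
#' @param layer Conv layer to analyse.
#' @param grids Grid sizes.
#' @return The feature table (data frame), invisibly, with attribute
#'   `n_failed` and the failed paths in attribute `failures`.
#' @export
run_extract <- function(paths, out = NULL, cfg = backbone_config(),
                        layer = 1L, grids = seq(2L, 30L, 2L)) {
  if (length(paths) < 1L) stop("usage error: no input images given")
  cfg_hash <- object_hash(cfg[c("weight_source", "input_size", "layers",
                                "apply_relu", "apply_pool_between_layers",
                                "seed")])
  rows <- list(); failed <- character(0)
  for (p in paths) {
    fv <- tryCatch({
      img <- load_and_preprocess(p, cfg)
      variance_features(extract_responses(img, cfg, layer), grids)
    }, error = function(e) {
      warning("skipping ", p, ": ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (!is.null(fv)) rows[[p]] <- fv else failed <- c(failed, p)
  }
  if (!length(rows)) stop("no input image could be processed")
  tab <- data.frame(image_id = basename(names(rows)),
                    layer = layer, config_hash = cfg_hash,
                    do.call(rbind, lapply(rows, unclass)),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(out)) write.csv(tab, out, row.names = FALSE)
  attr(tab, "n_failed") <- length(failed)
  attr(tab, "failures") <- failed
  invisible(tab)
}

#' Rank feature subsets of an extracted table by CV accuracy
#'
#' @param table Labeled feature table (data frame or CSV path).
#' @param max_size Largest subset size (1..3).
#' @param seed Fold seed.
#' @param out Optional CSV path for the ranked subsets.
#' @return The ranked data frame from [subset_search()], invisibly.
#' @export
run_classify <- function(table, max_size = 2L, seed = 17L, out = NULL) {
  if (is.character(table)) table <- read.csv(table, stringsAsFactors = FALSE)
  ranked <- subset_search(table, max_size = max_size, seed = seed)
  if (!is.null(out)) write.csv(ranked, out, row.names = FALSE)
  invisible(ranked)
}

#' Write a demo set of synthetic images and its manifest
#'
#' @param n_per_class Images per class.
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @param ... Passed to [synthetic_spec()].
#' @return The `synthetic_set`, invisibly.
#' @export
run_demo <- function(n_per_class = 50L, out_dir, seed = 1L, ...) {
  invisible(generate_labeled_set(n_per_class, seed = seed, dir = out_dir, ...))
}

#' Self-similarity scores for image files
#'
#' @inheritParams run_extract
#' @return Data frame with `image_id` and `selfsim`, invisibly.
#' @export
run_selfsim <- function(paths, out = NULL, cfg = backbone_config(),
                        layer = 1L) {
  if (length(paths) < 1L) stop("usage error: no input images given")
  ss <- vapply(paths, function(p) {
    self_similarity(extract_responses(load_and_preprocess(p, cfg), cfg, layer))
  }, numeric(1))
  tab <- data.frame(image_id = basename(paths), selfsim = unname(ss),
                    stringsAsFactors = FALSE)
  if (!is.null(out)) write.csv(tab, out, row.names = FALSE)
  invisible(tab)
}

#' Scatter plot of two features, colored by category
#'
#' A schematic view of the two-feature discrimination plane (classically
#' the richness measure at grid 22 against the variability measure at grid
#' 12).
#'
#' @param table Labeled feature table (data frame or CSV path).
#' @param feature_x,feature_y Feature column names.
#' @param out PNG output path.
#' @return `out`, invisibly.
#' @export
run_scatter <- function(table, feature_x = "Pa_22", feature_y = "Pf_12",
                        out = "scatter.png") {
  if (is.character(table)) table <- read.csv(table, stringsAsFactors = FALSE)
  if (nrow(table) == 0L) stop("empty feature table")
  for (f in c(feature_x, feature_y))
    if (!f %in% colnames(table)) stop("unknown feature: ", f)
  cats <- factor(table$category %||% "image")
  grDevices::png(out, width = 800, height = 600)
  on.exit(grDevices::dev.off())
  graphics::plot(table[[feature_x]], table[[feature_y]],
                 col = as.integer(cats), pch = 19,
                 xlab = feature_x, ylab = feature_y,
                 main = sprintf("%s vs %s", feature_y, feature_x))
  graphics::legend("topright", legend = levels(cats),
                   col = seq_along(levels(cats)), pch = 19)
  invisible(out)
}
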