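#' Specify a synthetic image
#'
#' Seeded, parameterized image classes emulating the category structure the
#' variance measures are meant to resolve:
#'
#' * `art_like` — dense multi-color, multi-orientation elements whose motif
#'   is resampled per tile with probability `variability` (rich *and*
#'   variable);
#' * `pattern_like` — one motif tiled over the whole canvas with
#'   near-zero variability (rich but self-similar, like plant patterns);
#' * `sparse_like` — a large smoothly shaded homogeneous field with at most
#'   `element_density` of the area covered by structured elements (like a
#'   large-vista scene or a plain object background);
#' * `noise` — i.i.d. uniform RGB pixels.
#'
#' @param class One of `"art_like"`, `"pattern_like"`, `"sparse_like"`,
#'   `"noise"`.
#' @param size Square canvas side in pixels (default 512, min 64).
#' @param tile Motif tile side in pixels; must divide `size` (default 64).
#' @param palette_k Number of distinct palette colors (>= 2, default 6).
#' @param element_density Fraction of the canvas covered by structured
#'   elements in `sparse_like` images (default 0.05; 0 gives a
#'   constant-color image).
#' @param variability Probability that a tile deviates from the base motif;
#'   defaults per class: 0.9 (`art_like`), 0.02 (`pattern_like`), otherwise
#'   0.
#' @param seed Integer seed; generation is fully deterministic given the
#'   spec.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(class = c("art_like", "pattern_like",
                                     "sparse_like", "noise"),
                           size = 512L, tile = 64L, palette_k = 6L,
                           element_density = 0.05, variability = NULL,
                           seed = 1L) {
  class <- match.arg(class)
  size <- as.integer(size); tile <- as.integer(tile)
  if (size < 64L) stop("size must be >= 64")
  if (size %% tile != 0L)
    stop("parameter error: tile (", tile, ") must divide size (", size, ")")
  if (palette_k < 2L) stop("palette_k must be >= 2")
  variability <- variability %||%
    switch(class, art_like = 0.9, pattern_like = 0.02, 0)
  if (variability < 0 || variability > 1)
    stop("variability must be in [0, 1]")
  if (element_density < 0 || element_density > 1)
    stop("element_density must be in [0, 1]")
  structure(list(class = class, size = size, tile = tile,
                 palette_k = as.integer(palette_k),
                 element_density = element_density,
                 variability = variability, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Seeded palette: evenly spread hues with jitter, varied saturation/value.
make_palette <- function(k) {
  h <- ((seq_len(k) - 1) / k + runif(1)) %% 1
  s <- runif(k, 0.45, 0.95)
  v <- runif(k, 0.35, 0.95)
  t(grDevices::col2rgb(grDevices::hsv(h, s, v)) / 255)
}

# A motif: a two-color in-tile gradient background plus a fixed arrangement
# of oriented bars and disks at 2-4 scales. Rendering is deterministic
# given the motif, so identical motifs tile into identical patches.
sample_motif <- function(palette, n_elements = 8L) {
  k <- nrow(palette)
  bgi <- sample.int(k, 2L)
  elements <- lapply(seq_len(n_elements), function(i) {
    list(type = sample(c("bar", "disk"), 1L, prob = c(0.6, 0.4)),
         cx = runif(1, 0.08, 0.92), cy = runif(1, 0.08, 0.92),
         size = runif(1, 0.12, 0.45),
         theta = runif(1, 0, pi),
         aspect = runif(1, 0.15, 0.4),
         col = palette[sample.int(k, 1L), ])
  })
  list(bg1 = palette[bgi[1], ], bg2 = palette[bgi[2], ],
       bg_theta = runif(1, 0, pi), elements = elements)
}

render_motif <- function(motif, t) {
  u <- (seq_len(t) - 0.5) / t
  U <- matrix(rep(u, each = t), t)  # column coordinate in [0,1]
  V <- matrix(rep(u, times = t), t) # row coordinate
  w <- U * cos(motif$bg_theta) + V * sin(motif$bg_theta)
  w <- (w - min(w)) / max(max(w) - min(w), 1e-12)
  tileimg <- array(0, c(t, t, 3))
  for (c in 1:3)
    tileimg[, , c] <- motif$bg1[c] * (1 - w) + motif$bg2[c] * w
  for (e in motif$elements) {
    xr <- (U - e$cx) * cos(e$theta) + (V - e$cy) * sin(e$theta)
    yr <- -(U - e$cx) * sin(e$theta) + (V - e$cy) * cos(e$theta)
    mask <- if (e$type == "bar")
      abs(xr) < e$size / 2 & abs(yr) < e$size * e$aspect / 2
    else (xr^2 + yr^2) < (e$size / 2)^2
    if (any(mask))
      for (c in 1:3) {
        ch <- tileimg[, , c]
        ch[mask] <- e$col[c]
        tileimg[, , c] <- ch
      }
  }
  tileimg
}

#' Generate a synthetic image
#'
#' Deterministic given the spec (including its seed); see
#' [synthetic_spec()] for the class contracts.
#'
#' @param spec A `synthetic_spec`.
#' @return An `image_rgb` array of `spec$size x spec$size x 3`.
#' @examples
#' img <- generate_image(synthetic_spec("pattern_like", size = 128, seed = 3))
#' range(img)
#' @export
generate_image <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  img <- with_seed(spec$seed, {
    pal <- make_palette(spec$palette_k)
    switch(spec$class,
      noise = array(runif(spec$size^2 * 3), c(spec$size, spec$size, 3)),
      sparse_like = render_sparse(spec, pal),
      render_tiled(spec, pal))
  })
  img[img < 0] <- 0; img[img > 1] <- 1
  structure(img, spec = spec, source_path = NA_character_,
            class = c("image_rgb", "array"))
}

render_tiled <- function(spec, pal) {
  nt <- spec$size %/% spec$tile
  base <- sample_motif(pal)
  canvas <- array(0, c(spec$size, spec$size, 3))
  for (ti in seq_len(nt)) for (tj in seq_len(nt)) {
    motif <- if (runif(1) < spec$variability) sample_motif(pal) else base
    rows <- (ti - 1L) * spec$tile + seq_len(spec$tile)
    cols <- (tj - 1L) * spec$tile + seq_len(spec$tile)
    canvas[rows, cols, ] <- render_motif(motif, spec$tile)
  }
  canvas
}

# Homogeneous field: a single smoothly shaded background (one dominant
# color, gentle large-scale gradient, as in a sky or plain backdrop) plus a
# few isolated elements capped at `element_density` of the area.
render_sparse <- function(spec, pal) {
  s <- spec$size
  base <- pal[sample.int(nrow(pal), 1L), ]
  if (spec$element_density == 0)
    return(array(rep(base, each = s * s), c(s, s, 3)))
  other <- pal[sample.int(nrow(pal), 1L), ]
  theta <- runif(1, 0, pi)
  u <- (seq_len(s) - 0.5) / s
  U <- matrix(rep(u, each = s), s)
  V <- matrix(rep(u, times = s), s)
  w <- U * cos(theta) + V * sin(theta)
  w <- (w - min(w)) / max(max(w) - min(w), 1e-12)
  canvas <- array(0, c(s, s, 3))
  amp <- runif(1, 0.15, 0.35) # gentle shading, field stays homogeneous
  for (c in 1:3)
    canvas[, , c] <- base[c] + amp * (w - 0.5) * (other[c] - base[c])
  r_elem <- s / 16
  n_elem <- max(1L, round(spec$element_density * s^2 / (pi * r_elem^2)))
  for (i in seq_len(n_elem)) {
    cx <- runif(1, 0.1, 0.9); cy <- runif(1, 0.1, 0.9)
    col <- pal[sample.int(nrow(pal), 1L), ]
    rr <- r_elem / s * runif(1, 0.6, 1.2)
    if (runif(1) < 0.5) {
      mask <- ((U - cx)^2 + (V - cy)^2) < rr^2
    } else {
      th <- runif(1, 0, pi)
      xr <- (U - cx) * cos(th) + (V - cy) * sin(th)
      yr <- -(U - cx) * sin(th) + (V - cy) * cos(th)
      mask <- abs(xr) < rr * 1.6 & abs(yr) < rr * 0.5
    }
    for (c in 1:3) {
      ch <- canvas[, , c]
      ch[mask] <- col[c]
      canvas[, , c] <- ch
    }
  }
  canvas
}

#' Generate a balanced labeled set of synthetic images
#'
#' Draws one independent sub-seed per image from `seed`, producing a
#' balanced manifest over the four classes with `art_like` labeled `art`
#' and the others `non_art`. Images are represented as specs and generated
#' on demand (see [feature_table_from_set()]), so arbitrarily large sets
#' stay cheap to describe; `dir` materializes them as PNGs plus a
#' `manifest.csv`.
#'
#' @param n_per_class Images per class (>= 10 for downstream CV).
#' @param seed Master seed.
#' @param classes Classes to include.
#' @param dir Optional output directory for PNGs and the manifest.
#' @param ... Passed to [synthetic_spec()] (e.g. `size`).
#' @return A `synthetic_set`: list with `manifest` (data frame) and `specs`.
#' @export
generate_labeled_set <- function(n_per_class = 25L, seed = 1L,
                                 classes = c("art_like", "pattern_like",
                                             "sparse_like", "noise"),
                                 dir = NULL, ...) {
  if (n_per_class < 10L) stop("n_per_class must be >= 10")
  n <- n_per_class * length(classes)
  sub_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  cls <- rep(classes, each = n_per_class)
  manifest <- data.frame(
    image_id = sprintf("%s_%03d", cls, rep(seq_len(n_per_class),
                                           length(classes))),
    class = cls,
    label = ifelse(cls == "art_like", "art", "non_art"),
    category = cls,
    seed = sub_seeds,
    stringsAsFactors = FALSE)
  specs <- lapply(seq_len(n), function(i)
    synthetic_spec(cls[i], seed = sub_seeds[i], ...))
  set <- structure(list(manifest = manifest, specs = specs),
                   class = "synthetic_set")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n))
      write_image_png(generate_image(specs[[i]]),
                      file.path(dir, paste0(manifest$image_id[i], ".png")))
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  set
}

#' @export
print.synthetic_set <- function(x, ...) {
  cat(sprintf("<synthetic_set> %d images: %s\n", nrow(x$manifest),
              paste(sprintf("%s=%d", names(table(x$manifest$class)),
                            table(x$manifest$class)), collapse = ", ")))
  invisible(x)
}

#' Variance features for every image of a synthetic set
#'
#' Generates each image, runs it through the backbone, computes the
#' 45-value feature vector (and optionally the self-similarity score) and
#' returns the labeled feature table ready for [cv_evaluate()].
#'
#' @param set A `synthetic_set` from [generate_labeled_set()].
#' @param cfg A [backbone_config()].
#' @param layer Conv layer to analyse.
#' @param grids Grid sizes (default 2..30 step 2).
#' @param selfsim Also compute [self_similarity()] per image (column
#'   `selfsim`)?
#' @return A labeled feature table (see [labeled_feature_table()]) with the
#'   extra column `selfsim` when requested.
#' @export
feature_table_from_set <- function(set, cfg = backbone_config(),
                                   layer = 1L, grids = seq(2L, 30L, 2L),
                                   selfsim = FALSE) {
  stopifnot(inherits(set, "synthetic_set"))
  n <- length(set$specs)
  rows <- vector("list", n)
  ss <- numeric(n)
  for (i in seq_len(n)) {
    resp <- extract_responses(generate_image(set$specs[[i]]), cfg, layer)
    rows[[i]] <- variance_features(resp, grids)
    if (selfsim) ss[i] <- self_similarity(resp)
  }
  fmat <- do.call(rbind, lapply(rows, unclass))
  tab <- labeled_feature_table(fmat, set$manifest$label,
                               set$manifest$category,
                               set$manifest$image_id)
  if (selfsim) tab$selfsim <- ss
  tab
}
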