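#' Max-pool a response stack over an n x n subregion grid
#'
#' Partitions every filter-response map into `n x n` near-equally sized
#' subregions and records the highest response of each filter in each
#' subregion. When the map side `H` is not divisible by `n`, subregion
#' boundaries fall at `round(j * H / n)`, so bin sizes differ by at most one
#' pixel and no pixels are dropped.
#'
#' @param resp A `response_stack` from [extract_responses()], or a plain
#'   `H x W x k` array.
#' @param n Grid size (subregions per axis); `1 <= n <= min(H, W)`.
#' @return A `max_pool_map`: list with `values` (`n x n x k` array of
#'   subregion maxima), `grid`, `layer_id`, `normalized = FALSE`.
#' @seealso [normalize_histograms()], [p_a()], [p_g()], [p_f()]
#' @export
max_pool_map <- function(resp, n) {
  maps <- if (inherits(resp, "response_stack")) resp$maps else resp
  if (is.matrix(maps)) maps <- array(maps, c(dim(maps), 1L))
  d <- dim(maps)
  n <- as.integer(n)
  if (n < 1L) stop("grid size n must be >= 1")
  if (n > min(d[1], d[2]))
    stop(sprintf("invalid grid: n = %d exceeds map size %d x %d",
                 n, d[1], d[2]))
  br <- grid_breaks(d[1], n)
  bc <- grid_breaks(d[2], n)
  structure(list(values = cpp_pool_max(maps, br, bc),
                 grid = n,
                 layer_id = if (inherits(resp, "response_stack"))
                   resp$layer_id else NA_integer_,
                 normalized = FALSE),
            class = "max_pool_map")
}

# 0-based near-equal bin edges: round(j * H / n), j = 0..n.
grid_breaks <- function(H, n) as.integer(round((0:n) * H / n))

#' L1-normalize the subregion histograms of a max-pool map
#'
#' Divides each subregion's vector of `k` filter maxima by its sum, so every
#' subregion histogram sums to one and the downstream variance measures are
#' invariant to global response scaling. Subregions in which no filter
#' responded at all (an all-zero vector, possible after rectification of a
#' perfectly flat region) are filled with the uniform histogram `1/k`; the
#' count of such fills is recorded in attribute `n_uniform_filled`.
#' Idempotent.
#'
#' @param m A `max_pool_map`.
#' @return The same map with unit-sum subregion histograms and
#'   `normalized = TRUE`.
#' @export
normalize_histograms <- function(m) {
  stopifnot(inherits(m, "max_pool_map"))
  v <- m$values
  if (any(v < 0))
    stop("negative pooled responses: histograms require rectified ",
         "(non-negative) filter responses")
  d <- dim(v)
  mat <- matrix(v, d[1] * d[2], d[3])
  s <- rowSums(mat)
  zero <- s == 0
  if (any(zero)) mat[zero, ] <- 1 / d[3]
  if (any(!zero)) mat[!zero, ] <- mat[!zero, , drop = FALSE] / s[!zero]
  m$values <- array(mat, d)
  m$normalized <- TRUE
  attr(m, "n_uniform_filled") <-
    (attr(m, "n_uniform_filled") %||% 0L) + sum(zero)
  m
}

#' @export
print.max_pool_map <- function(x, ...) {
  cat(sprintf("<max_pool_map> grid %d x %d, %d filters, %s\n",
              x$grid, x$grid, dim(x$values)[3],
              if (x$normalized) "normalized" else "raw maxima"))
  invisible(x)
}

check_normalized <- function(m, what) {
  if (!inherits(m, "max_pool_map"))
    stop(what, "() expects a max_pool_map")
  if (!isTRUE(m$normalized))
    stop(what, "() requires a normalized map; call normalize_histograms() first")
  m
}

#' Richness measure: total variance over all histogram entries
#'
#' The variance over all `n * n * k` entries of the normalized max-pooling
#' map. High values indicate sparse subregion histograms (few filters
#' dominate each subregion, as in homogeneous images); the measure
#' approaches zero when all filters in all subregions are activated to the
#' same degree, the signature of response *richness*.
#'
#' @param m A normalized `max_pool_map`.
#' @param estimator `"population"` (divide by the count; default) or
#'   `"sample"`.
#' @return A non-negative scalar.
#' @export
p_a <- function(m, estimator = c("population", "sample")) {
  m <- check_normalized(m, "p_a")
  variance_of(as.vector(m$values), match.arg(estimator))
}

#' Median within-subregion histogram variance
#'
#' For each of the `n * n` subregions, the variance over its `k` histogram
#' entries; the measure is the median of these per-subregion variances.
#'
#' @inheritParams p_a
#' @return A non-negative scalar.
#' @export
p_g <- function(m, estimator = c("population", "sample")) {
  m <- check_normalized(m, "p_g")
  estimator <- match.arg(estimator)
  d <- dim(m$values)
  mat <- matrix(m$values, d[1] * d[2], d[3])
  v <- pmax(rowMeans(mat^2) - rowMeans(mat)^2, 0)
  if (estimator == "sample") v <- v * d[3] / (d[3] - 1)
  median(v)
}

#' Variability measure: median per-filter variance across subregions
#'
#' For each filter, the variance of its `n * n` subregion maxima (after
#' histogram normalization); the measure is the median over the `k` filters.
#' It behaves as the inverse of self-similarity: when each filter responds
#' equally in every subregion the measure is zero.
#'
#' @inheritParams p_a
#' @return A non-negative scalar.
#' @export
p_f <- function(m, estimator = c("population", "sample")) {
  m <- check_normalized(m, "p_f")
  estimator <- match.arg(estimator)
  d <- dim(m$values)
  nn <- d[1] * d[2]
  mat <- matrix(m$values, nn, d[3])
  v <- pmax(colMeans(mat^2) - colMeans(mat)^2, 0)
  if (estimator == "sample") v <- v * nn / (nn - 1)
  median(v)
}

#' Names of the 45 variance features, in their fixed column order
#'
#' Grouped by measure, then grid size: `Pa_2 ... Pa_30, Pg_2 ... Pg_30,
#' Pf_2 ... Pf_30`.
#'
#' @param grids Grid sizes (default 2, 4, ..., 30).
#' @return Character vector of feature names.
#' @export
variance_feature_names <- function(grids = seq(2L, 30L, 2L)) {
  as.vector(vapply(c("Pa", "Pg", "Pf"),
                   function(p) paste0(p, "_", grids),
                   character(length(grids))))
}

#' The 45-value variance feature vector of one response stack
#'
#' Computes the three variance measures ([p_a()], [p_g()], [p_f()]) on
#' normalized max-pooling maps for grid sizes 2 to 30 in steps of 2 —
#' 3 measures x 15 grids = 45 values per layer. Column order is fixed:
#' grouped by measure, then grid size (see [variance_feature_names()]).
#'
#' @param resp A `response_stack` (or `H x W x k` array) with
#'   `min(H, W) >= max(grids)`.
#' @param grids Grid sizes; default `seq(2, 30, 2)`.
#' @param estimator Variance estimator, as in [p_a()].
#' @return A named numeric vector of class `variance_features`, with
#'   attributes `layer_id`, `grids` and `n_uniform_filled` (total count of
#'   degenerate all-zero subregions encountered).
#' @examples
#' cfg <- backbone_config("gabor", input_size = 128)
#' img <- generate_image(synthetic_spec("art_like", size = 128, seed = 1))
#' fv <- variance_features(extract_responses(img, cfg))
#' length(fv) # 45
#' fv[c("Pa_22", "Pf_12")]
#' @export
variance_features <- function(resp, grids = seq(2L, 30L, 2L),
                              estimator = c("population", "sample")) {
  estimator <- match.arg(estimator)
  maps <- if (inherits(resp, "response_stack")) resp$maps else resp
  d <- dim(maps)
  if (min(d[1], d[2]) < max(grids))
    stop(sprintf("response maps are %d x %d but the largest grid is %d; ",
                 d[1], d[2], max(grids)),
         "maps must be at least as large as the largest grid per axis")
  filled <- 0L
  vals <- lapply(grids, function(n) {
    m <- normalize_histograms(max_pool_map(resp, n))
    filled <<- filled + attr(m, "n_uniform_filled")
    c(p_a(m, estimator), p_g(m, estimator), p_f(m, estimator))
  })
  vm <- do.call(rbind, vals) # one row per grid: Pa, Pg, Pf
  out <- c(vm[, 1], vm[, 2], vm[, 3])
  names(out) <- variance_feature_names(grids)
  structure(out,
            layer_id = if (inherits(resp, "response_stack"))
              resp$layer_id else NA_integer_,
            grids = as.integer(grids),
            n_uniform_filled = filled,
            class = c("variance_features", "numeric"))
}

#' @export
print.variance_features <- function(x, ...) {
  cat(sprintf("<variance_features> layer %s, %d values (%d grids x 3 measures)\n",
              attr(x, "layer_id"), length(x), length(attr(x, "grids"))))
  print(unclass(x)[seq_len(min(6L, length(x)))])
  if (length(x) > 6L) cat("...\n")
  invisible(x)
}

#' Self-similarity of an image's filter responses
#'
#' Compares the whole-image ("ground level") normalized response histogram
#' — the max pool over the entire map, grid 1 — against the histograms of
#' `n_sub^2` equally sized subregions (8 x 8 = 64 by default). Each
#' subregion histogram is compared to the ground histogram by histogram
#' intersection, `sum_i min(g_i, h_i)`, and the intersections are averaged.
#' The score lies in `[0, 1]` and equals 1 exactly when every subregion
#' histogram equals the ground histogram.
#'
#' @param resp A `response_stack` (or array) with maps at least
#'   `n_sub x n_sub`.
#' @param n_sub Subregion grid side (default 8).
#' @return Scalar self-similarity in `[0, 1]`.
#' @export
self_similarity <- function(resp, n_sub = 8L) {
  maps <- if (inherits(resp, "response_stack")) resp$maps else resp
  d <- dim(maps)
  if (min(d[1], d[2]) < n_sub)
    stop("response maps must be at least ", n_sub, " x ", n_sub)
  g <- normalize_histograms(max_pool_map(resp, 1L))
  h <- normalize_histograms(max_pool_map(resp, n_sub))
  k <- d[3]
  gvec <- as.vector(g$values)
  hmat <- matrix(h$values, n_sub * n_sub, k)
  inter <- rowSums(pmin(hmat, matrix(gvec, n_sub * n_sub, k, byrow = TRUE)))
  mean(inter)
}
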