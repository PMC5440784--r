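# Independent reference implementations (explicit loops, base R) used to
# check the vectorized code paths, plus shared small fixtures.

# Brute-force subregion maxima with round(j * H / n) bin edges.
naive_pool_max <- function(maps, n) {
  d <- dim(maps)
  br <- round((0:n) * d[1] / n)
  bc <- round((0:n) * d[2] / n)
  out <- array(NA_real_, c(n, n, d[3]))
  for (f in seq_len(d[3]))
    for (i in seq_len(n))
      for (j in seq_len(n))
        out[i, j, f] <- max(maps[(br[i] + 1):br[i + 1],
                                 (bc[j] + 1):bc[j + 1], f])
  out
}

naive_normalize <- function(v) {
  d <- dim(v)
  for (i in seq_len(d[1]))
    for (j in seq_len(d[2])) {
      s <- sum(v[i, j, ])
      v[i, j, ] <- if (s == 0) rep(1 / d[3], d[3]) else v[i, j, ] / s
    }
  v
}

pop_var <- function(x) mean((x - mean(x))^2)

# Naive Eqs: total variance, median per-subregion variance, median
# per-filter variance, all population estimator, explicit loops.
naive_pa <- function(v) pop_var(as.vector(v))

naive_pg <- function(v) {
  d <- dim(v)
  vg <- numeric(0)
  for (i in seq_len(d[1]))
    for (j in seq_len(d[2]))
      vg <- c(vg, pop_var(v[i, j, ]))
  median(vg)
}

naive_pf <- function(v) {
  d <- dim(v)
  vf <- numeric(d[3])
  for (f in seq_len(d[3])) vf[f] <- pop_var(as.vector(v[, , f]))
  median(vf)
}

# A normalized max_pool_map built directly from an n x n x k value array.
as_norm_map <- function(values) {
  structure(list(values = values, grid = dim(values)[1], layer_id = 1L,
                 normalized = TRUE),
            class = "max_pool_map")
}

random_resp <- function(H, W, k, seed) {
  set.seed(seed)
  array(runif(H * W * k), c(H, W, k))
}

# Small-geometry backbone shared by plumbing tests: 128 px input maps to
# 30 x 30 first-layer responses, the smallest size supporting grid 30.
small_cfg <- function() backbone_config("gabor", input_size = 128L)

.fixtures <- new.env()

# Memoized small labeled feature table (40 images at 128 px).
small_table <- function(selfsim = TRUE) {
  if (is.null(.fixtures$tab)) {
    set <- generate_labeled_set(10L, seed = 7L, size = 128L, tile = 32L)
    .fixtures$tab <- feature_table_from_set(set, small_cfg(), selfsim = TRUE)
  }
  .fixtures$tab
}

# Well-separated two-class Gaussian table for classifier tests.
gaussian_table <- function(n = 200L, d = 2L, sep = 10, seed = 5L,
                           n_noise = 0L) {
  set.seed(seed)
  half <- n %/% 2L
  x <- rbind(matrix(rnorm(half * d), half),
             matrix(rnorm((n - half) * d, mean = sep), n - half))
  colnames(x) <- paste0("f", seq_len(d))
  if (n_noise > 0L) {
    nz <- matrix(rnorm(n * n_noise), n)
    colnames(nz) <- paste0("noise", seq_len(n_noise))
    x <- cbind(x, nz)
  }
  labeled_feature_table(x, c(rep("art", half), rep("non_art", n - half)),
                        category = c(rep("west", half),
                                     rep("photo", n - half)))
}

# Memoized study-condition feature tables: generator defaults (512 px,
# tile 64), gabor bank, 75 images per class (75 art vs 225 non-art).
study_table <- function(seed) {
  key <- paste0("study_", seed)
  if (is.null(.fixtures[[key]])) {
    set <- generate_labeled_set(75L, seed = seed)
    .fixtures[[key]] <- feature_table_from_set(set, backbone_config("gabor"),
                                               selfsim = (seed == 1L))
  }
  .fixtures[[key]]
}
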