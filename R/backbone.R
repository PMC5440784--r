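#' Output side length of a valid (unpadded-overhang-free) convolution
#'
#' Standard convolution geometry: `floor((in + 2 pad - kernel) / stride) + 1`.
#' The canonical first-layer case of an AlexNet-style backbone maps a
#' 227-pixel input through an 11-pixel kernel at stride 4 to 55 pixels, and a
#' 512-pixel input to 126 pixels.
#'
#' @param in_size Input side length in pixels.
#' @param kernel Kernel side length in pixels.
#' @param stride Stride in pixels (default 1).
#' @param padding Zero padding per side in pixels (default 0).
#' @return Output side length in pixels (integer).
#' @examples
#' conv_output_size(227, 11, 4) # 55
#' conv_output_size(512, 11, 4) # 126
#' @export
conv_output_size <- function(in_size, kernel, stride = 1L, padding = 0L) {
  stopifnot(length(in_size) == 1L, length(kernel) == 1L)
  if (stride < 1L) stop("stride must be >= 1")
  if (padding < 0L) stop("padding must be >= 0")
  if (in_size + 2L * padding < kernel)
    stop(sprintf("invalid geometry: kernel %d larger than padded input %d",
                 kernel, in_size + 2L * padding))
  as.integer(floor((in_size + 2 * padding - kernel) / stride) + 1)
}

#' Describe one convolutional layer
#'
#' @param kernel,stride,padding Convolution geometry in pixels.
#' @param filters Number of filters `k` in the layer.
#' @return A `conv_layer` descriptor list.
#' @export
conv_layer <- function(kernel = 11L, stride = 4L, padding = 0L, filters = 30L) {
  structure(list(kernel = as.integer(kernel), stride = as.integer(stride),
                 padding = as.integer(padding), filters = as.integer(filters)),
            class = "conv_layer")
}

#' Configure the convolution-only backbone
#'
#' The backbone is the convolutional front end through which images are
#' passed before the max-pooling variance measures are computed: fully
#' connected layers are dropped and the input is rescaled to a square of
#' `input_size` pixels (512 by default) while the filter geometry keeps its
#' original parameters. Three weight sources are supported:
#'
#' * `"gabor"` — a deterministic analytic bank of 30 filters: oriented
#'   even/odd Gabor patches at 4 orientations and 2 wavelengths on the
#'   luminance channel, centre-surround (difference-of-Gaussians) filters on
#'   the luminance, red-green and blue-yellow opponent channels at 2 scales,
#'   and oriented first-derivative-of-Gaussian color-edge filters on both
#'   opponent channels. Qualitatively mirrors the oriented-edge and
#'   opponent-color structure of a trained first layer without requiring any
#'   download.
#' * `"random"` — seeded i.i.d. Gaussian filters, zero-mean and unit-norm
#'   per filter; supports multiple layers.
#' * `"pretrained"` — first-layer weights loaded from a plain-text matrix
#'   (`weights_file`, CSV/TSV, one row per filter, `kernel^2 * 3` columns in
#'   row-fastest, then column, then R/G/B channel order); 96 filters are
#'   required, matching the first convolutional layer of the original model.
#'
#' Preprocessing: for builtin banks the image stays in `[0, 1]` RGB and the
#' per-channel image mean is removed; for pretrained weights the fixed
#' channel means in `channel_means` are subtracted instead (defaults are the
#' usual ImageNet means on the `[0, 1]` scale). Because subregion histograms
#' are later L1-normalized, any global response scaling cancels.
#'
#' @param weight_source `"gabor"`, `"random"` or `"pretrained"`.
#' @param input_size Square input side length in pixels (default 512).
#' @param layers List of [conv_layer()] descriptors; default a single
#'   11-pixel kernel, stride-4, unpadded layer.
#' @param apply_relu Rectify responses (half-wave, `max(x, 0)`)? Default
#'   `TRUE`; the variance measures are defined on non-negative responses.
#' @param apply_pool_between_layers Insert 2x2 stride-2 max pooling between
#'   successive conv layers (only relevant when analysing layers >= 2)?
#' @param seed Integer seed for the `"random"` bank.
#' @param weights_file Path to the pretrained weight matrix (see above).
#' @param channel_means Per-channel means subtracted for pretrained weights.
#' @return A `backbone_config` object with materialized per-layer weights.
#' @examples
#' cfg <- backbone_config("gabor", input_size = 256)
#' cfg
#' @export
backbone_config <- function(weight_source = c("gabor", "random", "pretrained"),
                            input_size = 512L,
                            layers = list(conv_layer()),
                            apply_relu = TRUE,
                            apply_pool_between_layers = FALSE,
                            seed = 1L,
                            weights_file = NULL,
                            channel_means = c(0.485, 0.456, 0.406)) {
  weight_source <- match.arg(weight_source)
  stopifnot(is.list(layers), length(layers) >= 1L)
  layers <- lapply(layers, function(l) {
    if (!inherits(l, "conv_layer")) do.call(conv_layer, l) else l
  })
  if (input_size < layers[[1]]$kernel)
    stop("input_size must be at least the first-layer kernel size")
  weights <- switch(weight_source,
    gabor = {
      if (length(layers) > 1L)
        stop("the analytic gabor bank defines a single layer")
      w <- filter_bank_gabor(layers[[1]]$kernel)
      layers[[1]]$filters <- ncol(w)
      list(w)
    },
    random = {
      in_ch <- 3L
      ws <- vector("list", length(layers))
      for (i in seq_along(layers)) {
        ws[[i]] <- filter_bank_random(layers[[i]]$kernel, in_ch,
                                      layers[[i]]$filters,
                                      seed = seed + i - 1L)
        in_ch <- layers[[i]]$filters
      }
      ws
    },
    pretrained = {
      if (is.null(weights_file) || !file.exists(weights_file %||% ""))
        stop("pretrained weights not available: supply `weights_file` ",
             "(one row per filter), or use weight_source = \"random\" or ",
             "\"gabor\" for a builtin bank", call. = FALSE)
      if (length(layers) > 1L)
        stop("pretrained mode supports the first convolutional layer only")
      w <- as.matrix(read.csv(weights_file, header = FALSE,
                              sep = if (grepl("\\.tsv$", weights_file)) "\t" else ","))
      if (nrow(w) != 96L)
        stop("pretrained first-layer bank must hold 96 filters, got ", nrow(w))
      if (ncol(w) != layers[[1]]$kernel^2 * 3L)
        stop("pretrained weight row length ", ncol(w), " does not match ",
             "kernel geometry (", layers[[1]]$kernel^2 * 3L, ")")
      layers[[1]]$filters <- 96L
      list(t(w))
    })
  structure(list(weight_source = weight_source,
                 input_size = as.integer(input_size),
                 layers = layers, weights = weights,
                 apply_relu = isTRUE(apply_relu),
                 apply_pool_between_layers = isTRUE(apply_pool_between_layers),
                 seed = as.integer(seed),
                 channel_means = channel_means),
            class = "backbone_config")
}

#' @export
print.backbone_config <- function(x, ...) {
  cat(sprintf("<backbone_config> source=%s input=%dpx layers=%d relu=%s\n",
              x$weight_source, x$input_size, length(x$layers), x$apply_relu))
  for (i in seq_along(x$layers)) {
    l <- x$layers[[i]]
    cat(sprintf("  conv%d: kernel %d, stride %d, pad %d, %d filters\n",
                i, l$kernel, l$stride, l$padding, l$filters))
  }
  invisible(x)
}

# Seeded random filter bank: (kernel^2 * in_ch) x k matrix, each column
# zero-mean with unit L2 norm.
filter_bank_random <- function(kernel, in_ch, k, seed = 1L) {
  w <- with_seed(seed, matrix(rnorm(kernel^2 * in_ch * k), ncol = k))
  w <- sweep(w, 2, colMeans(w))
  sweep(w, 2, sqrt(colSums(w^2)), "/")
}

# Deterministic analytic bank: 16 luminance Gabors + 6 opponent/luminance
# centre-surround + 8 opponent colour-edge filters = 30 filters.
filter_bank_gabor <- function(kernel = 11L) {
  half <- (kernel - 1) / 2
  g <- seq(-half, half)
  X <- matrix(rep(g, each = kernel), kernel)   # column coordinate
  Y <- matrix(rep(g, times = kernel), kernel)  # row coordinate
  lum <- c(1, 1, 1) / 3
  rg <- c(1, -1, 0)
  by <- c(0.5, 0.5, -1)
  spatial <- list(); chans <- list()
  gabor <- function(theta, lambda, phase) {
    xr <- X * cos(theta) + Y * sin(theta)
    yr <- -X * sin(theta) + Y * cos(theta)
    sigma <- lambda / 2
    exp(-(xr^2 + yr^2) / (2 * sigma^2)) * cos(2 * pi * xr / lambda + phase)
  }
  dog <- function(s1, s2) {
    exp(-(X^2 + Y^2) / (2 * s1^2)) / s1^2 - exp(-(X^2 + Y^2) / (2 * s2^2)) / s2^2
  }
  dgauss <- function(theta, sigma) {
    xr <- X * cos(theta) + Y * sin(theta)
    -xr / sigma^2 * exp(-(X^2 + Y^2) / (2 * sigma^2))
  }
  for (theta in c(0, 45, 90, 135) * pi / 180)
    for (lambda in c(4, 8))
      for (phase in c(0, pi / 2)) {
        spatial[[length(spatial) + 1L]] <- gabor(theta, lambda, phase)
        chans[[length(chans) + 1L]] <- lum
      }
  for (ch in list(lum, rg, by))
    for (s in list(c(1, 2), c(2, 4))) {
      spatial[[length(spatial) + 1L]] <- dog(s[1], s[2])
      chans[[length(chans) + 1L]] <- ch
    }
  for (ch in list(rg, by))
    for (theta in c(0, 45, 90, 135) * pi / 180) {
      spatial[[length(spatial) + 1L]] <- dgauss(theta, 2)
      chans[[length(chans) + 1L]] <- ch
    }
  w <- vapply(seq_along(spatial), function(i) {
    s <- spatial[[i]] - mean(spatial[[i]])  # exact zero DC response
    as.vector(outer(as.vector(s), chans[[i]]))
  }, numeric(kernel^2 * 3L))
  sweep(w, 2, sqrt(colSums(w^2)), "/")
}

# Cache of im2col gather indices, keyed by geometry.
.im2col_cache <- new.env(parent = emptyenv())

im2col_indices <- function(H, W, C, kh, kw, stride) {
  key <- paste(H, W, C, kh, kw, stride, sep = "_")
  hit <- .im2col_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hout <- conv_output_size(H, kh, stride)
  Wout <- conv_output_size(W, kw, stride)
  r0 <- (seq_len(Hout) - 1L) * stride
  c0 <- (seq_len(Wout) - 1L) * stride
  pos <- rep(r0, times = Wout) + rep(c0, each = Hout) * H
  du <- rep(seq_len(kh) - 1L, times = kw * C)
  dv <- rep(rep(seq_len(kw) - 1L, each = kh), times = C)
  dc <- rep(seq_len(C) - 1L, each = kh * kw)
  off <- du + dv * H + dc * (H * W)
  idx <- as.vector(outer(as.integer(pos), as.integer(off), "+")) + 1L
  res <- list(idx = idx, n_pos = Hout * Wout, Hout = Hout, Wout = Wout)
  .im2col_cache[[key]] <- res
  res
}

# Valid strided convolution of an H x W x C array with a (kh*kw*C) x k
# weight matrix, via patch gathering and one BLAS product.
conv_strided <- function(x, w, kernel, stride, padding = 0L) {
  if (padding > 0L) {
    d <- dim(x)
    xp <- array(0, c(d[1] + 2L * padding, d[2] + 2L * padding, d[3]))
    xp[padding + seq_len(d[1]), padding + seq_len(d[2]), ] <- x
    x <- xp
  }
  d <- dim(x)
  ic <- im2col_indices(d[1], d[2], d[3], kernel, kernel, stride)
  patches <- matrix(x[ic$idx], nrow = ic$n_pos)
  resp <- patches %*% w
  array(resp, c(ic$Hout, ic$Wout, ncol(w)))
}

#' Run an image through the backbone and collect one layer's responses
#'
#' Applies per-channel mean removal, then the configured convolutional
#' layers up to `layer` (rectifying between layers, and max pooling between
#' them when `cfg$apply_pool_between_layers` is set), and returns the stack
#' of filter-response maps of the requested layer. Deterministic given
#' `(img, cfg)` including the configuration seed.
#'
#' @param img An `image_rgb` array (see [load_and_preprocess()] /
#'   [as_image_rgb()]). Must match `cfg$input_size`; if not, it is resized.
#' @param cfg A [backbone_config()].
#' @param layer 1-based index of the conv layer whose responses are wanted.
#' @return A `response_stack`: list with `maps` (`H_l x W_l x k` array,
#'   non-negative when `cfg$apply_relu`), `layer_id` and `geometry`.
#' @export
extract_responses <- function(img, cfg = backbone_config(), layer = 1L) {
  if (layer < 1L || layer > length(cfg$layers))
    stop("layer must be between 1 and ", length(cfg$layers))
  x <- unclass(img)
  if (length(dim(x)) != 3L || dim(x)[3] != 3L)
    stop("img must be an H x W x 3 array")
  if (dim(x)[1] != cfg$input_size || dim(x)[2] != cfg$input_size)
    x <- resize_bilinear(x, cfg$input_size, cfg$input_size)
  means <- if (cfg$weight_source == "pretrained") cfg$channel_means
           else apply(x, 3, mean)
  for (c in 1:3) x[, , c] <- x[, , c] - means[c]
  for (l in seq_len(layer)) {
    ly <- cfg$layers[[l]]
    x <- conv_strided(x, cfg$weights[[l]], ly$kernel, ly$stride, ly$padding)
    last <- l == layer
    if (!last || cfg$apply_relu) x[x < 0] <- 0
    if (!last && cfg$apply_pool_between_layers) {
      d <- dim(x)
      nb <- d[1] %/% 2L
      br <- as.integer(round(seq(0, d[1], length.out = nb + 1)))
      bc <- as.integer(round(seq(0, d[2], length.out = (d[2] %/% 2L) + 1)))
      x <- cpp_pool_max(x, br, bc)
    }
  }
  structure(list(maps = x, layer_id = as.integer(layer),
                 geometry = dim(x)[1:2]),
            class = "response_stack")
}

#' @export
print.response_stack <- function(x, ...) {
  cat(sprintf("<response_stack> layer %d: %d maps of %d x %d, range [%.4g, %.4g]\n",
              x$layer_id, dim(x$maps)[3], x$geometry[1], x$geometry[2],
              min(x$maps), max(x$maps)))
  invisible(x)
}
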