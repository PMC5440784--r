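#' Load an image and preprocess it for feature extraction
#'
#' Decodes a PNG, JPEG or TIFF file, rescales intensities to `[0, 1]`,
#' replicates grayscale images across three channels, drops an alpha channel
#' (with a warning) and resizes the image anisotropically to the backbone's
#' square input size with bilinear interpolation. No cropping is performed:
#' non-square inputs are stretched, the simplest faithful reading of
#' rescaling an image to a fixed input dimension.
#'
#' @param path Path to a PNG, JPEG or TIFF file.
#' @param cfg A [backbone_config()]; its `input_size` sets the output side
#'   length.
#' @return An `image_rgb` object: an `input_size x input_size x 3` numeric
#'   array with values in `[0, 1]` and attribute `source_path`.
#' @examples
#' f <- tempfile(fileext = ".png")
#' png::writePNG(array(runif(32 * 32 * 3), c(32, 32, 3)), f)
#' img <- load_and_preprocess(f, backbone_config("random", input_size = 64))
#' dim(img)
#' @export
load_and_preprocess <- function(path, cfg = backbone_config()) {
  x <- decode_image(path)
  img <- as_image_rgb(x, size = cfg$input_size, source_path = path)
  img
}

# Decode by file signature first, falling back to the extension.
decode_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  magic <- readBin(path, "raw", n = 4L)
  kind <- if (length(magic) >= 4L &&
              identical(magic, as.raw(c(0x89, 0x50, 0x4e, 0x47)))) "png"
  else if (length(magic) >= 2L &&
           identical(magic[1:2], as.raw(c(0xff, 0xd8)))) "jpeg"
  else if (length(magic) >= 2L &&
           (identical(magic[1:2], as.raw(c(0x49, 0x49))) ||
            identical(magic[1:2], as.raw(c(0x4d, 0x4d))))) "tiff"
  else tolower(tools::file_ext(path))
  if (kind %in% c("jpg", "jpeg")) kind <- "jpeg"
  if (kind %in% c("tif", "tiff")) kind <- "tiff"
  x <- switch(kind,
    png = try(png::readPNG(path), silent = TRUE),
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("reading JPEG requires the 'jpeg' package", call. = FALSE)
      try(jpeg::readJPEG(path), silent = TRUE)
    },
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package", call. = FALSE)
      try(tiff::readTIFF(path), silent = TRUE)
    },
    stop("unsupported image format for: ", path, call. = FALSE)
  )
  if (inherits(x, "try-error"))
    stop("failed to decode image: ", path, call. = FALSE)
  x
}

#' Coerce an array to a standard RGB image
#'
#' @param x Numeric matrix (grayscale) or `H x W x {1,3,4}` array, values in
#'   `[0, 1]`.
#' @param size Optional target side length; when given, the image is resized
#'   (bilinearly, anisotropically) to `size x size`.
#' @param source_path Optional provenance string stored as an attribute.
#' @return An `image_rgb` array (`H x W x 3`, values in `[0, 1]`).
#' @export
as_image_rgb <- function(x, size = NULL, source_path = NA_character_) {
  if (is.matrix(x)) x <- array(rep(x, 3L), c(dim(x), 3L))
  if (length(dim(x)) != 3L)
    stop("expected a matrix or 3-d array, got ", length(dim(x)), " dimensions")
  nc <- dim(x)[3]
  if (nc == 1L) x <- array(rep(x, 3L), c(dim(x)[1:2], 3L))
  if (nc == 4L) {
    warning("alpha channel dropped: ", source_path)
    x <- x[, , 1:3, drop = FALSE]
  }
  if (dim(x)[3] != 3L) stop("expected 1, 3 or 4 channels, got ", nc)
  if (anyNA(x) || any(!is.finite(x))) stop("image contains non-finite values")
  # 16-bit readers already scale to [0,1]; clamp rounding spill.
  x[x < 0] <- 0; x[x > 1] <- 1
  if (!is.null(size) && (dim(x)[1] != size || dim(x)[2] != size))
    x <- resize_bilinear(x, size, size)
  if (dim(x)[1] < 32L || dim(x)[2] < 32L)
    stop("image must be at least 32 x 32 pixels")
  structure(x, source_path = source_path, class = c("image_rgb", "array"))
}

# Bilinear resampling with half-pixel centre alignment.
resize_bilinear <- function(x, out_h, out_w) {
  H <- dim(x)[1]; W <- dim(x)[2]; k <- dim(x)[3]
  sy <- pmin(pmax((seq_len(out_h) - 0.5) * H / out_h - 0.5, 0), H - 1)
  sx <- pmin(pmax((seq_len(out_w) - 0.5) * W / out_w - 0.5, 0), W - 1)
  y0 <- floor(sy); x0 <- floor(sx)
  wy <- sy - y0; wx <- sx - x0
  y1 <- pmin(y0 + 1, H - 1); x1 <- pmin(x0 + 1, W - 1)
  out <- array(0, c(out_h, out_w, k))
  w00 <- (1 - wy) %o% (1 - wx); w01 <- (1 - wy) %o% wx
  w10 <- wy %o% (1 - wx); w11 <- wy %o% wx
  for (c in seq_len(k)) {
    ch <- x[, , c]
    out[, , c] <- w00 * ch[y0 + 1, x0 + 1] + w01 * ch[y0 + 1, x1 + 1] +
      w10 * ch[y1 + 1, x0 + 1] + w11 * ch[y1 + 1, x1 + 1]
  }
  out
}

#' Write an RGB image to a PNG file
#' @param img An `image_rgb` array.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  png::writePNG(unclass(img), path)
  invisible(path)
}

#' @export
print.image_rgb <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<image_rgb> %d x %d x %d, range [%.3f, %.3f]\n",
              d[1], d[2], d[3], min(x), max(x)))
  invisible(x)
}
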