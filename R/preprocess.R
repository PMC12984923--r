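#' Gaussian denoising of a grayscale image
#'
#' Convolves an intensity matrix with a normalized 2-D Gaussian kernel,
#' truncated at `4 * sigma` and applied with reflected borders, so constant
#' images and total interior intensity are preserved. `sigma = 0` is the
#' identity.
#'
#' @param image Numeric matrix of finite intensities (rows = y, cols = x).
#' @param sigma Kernel standard deviation in pixels, `>= 0`.
#' @return A matrix with the same dimensions as `image`.
#' @export
gaussian_denoise <- function(image, sigma = 1) {
  image <- as.matrix(image)
  if (!all(is.finite(image))) stop("invalid input: non-finite pixel values")
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0)
    stop("invalid argument: sigma must be a single value >= 0")
  if (sigma == 0) return(image)
  half <- max(1L, as.integer(ceiling(4 * sigma)))
  u <- seq(-half, half)
  k1 <- exp(-u^2 / (2 * sigma^2))
  k1 <- k1 / sum(k1)
  # separable convolution with reflected (edge-inclusive mirror) padding
  reflect_idx <- function(n) {
    left <- pmin(rev(seq_len(half)), n)
    right <- pmax(n + 1L - seq_len(half), 1L)
    c(left, seq_len(n), right)
  }
  conv_axis <- function(m) {
    n <- ncol(m)
    padded <- m[, reflect_idx(n), drop = FALSE]
    out <- matrix(0, nrow(m), n)
    for (o in seq_along(k1)) {
      out <- out + k1[o] * padded[, (o - 1) + seq_len(n), drop = FALSE]
    }
    out
  }
  t(conv_axis(t(conv_axis(image))))
}

#' Bilinear resizing with align-corners mapping
#'
#' Resamples an intensity matrix to the requested size. Output corner
#' samples coincide with input corner samples; interior samples are
#' bilinear interpolations. Resizing to the current size returns the input
#' unchanged.
#'
#' @param image Numeric matrix.
#' @param target_h,target_w Requested dimensions, `>= 1`.
#' @return A `target_h x target_w` matrix.
#' @export
bilinear_resize <- function(image, target_h, target_w) {
  image <- as.matrix(image)
  if (!all(is.finite(image))) stop("invalid input: non-finite pixel values")
  target_h <- as.integer(target_h); target_w <- as.integer(target_w)
  if (is.na(target_h) || is.na(target_w) || target_h < 1L || target_w < 1L)
    stop("invalid argument: target dimensions must be >= 1")
  h <- nrow(image); w <- ncol(image)
  if (target_h == h && target_w == w) return(image)
  src_y <- if (target_h == 1L) rep((h - 1) / 2, 1L) else
    (seq_len(target_h) - 1) * (h - 1) / (target_h - 1)
  src_x <- if (target_w == 1L) rep((w - 1) / 2, 1L) else
    (seq_len(target_w) - 1) * (w - 1) / (target_w - 1)
  y0 <- pmin(floor(src_y), h - 1); y0 <- pmax(y0, 0)
  x0 <- pmin(floor(src_x), w - 1); x0 <- pmax(x0, 0)
  y1 <- pmin(y0 + 1, h - 1); x1 <- pmin(x0 + 1, w - 1)
  fy <- src_y - y0; fx <- src_x - x0
  # gather the four neighbor grids (1-based indexing)
  A <- image[cbind(rep(y0 + 1, target_w), rep(x0 + 1, each = target_h))]
  B <- image[cbind(rep(y0 + 1, target_w), rep(x1 + 1, each = target_h))]
  C <- image[cbind(rep(y1 + 1, target_w), rep(x0 + 1, each = target_h))]
  D <- image[cbind(rep(y1 + 1, target_w), rep(x1 + 1, each = target_h))]
  FY <- rep(fy, target_w); FX <- rep(fx, each = target_h)
  vals <- A * (1 - FY) * (1 - FX) + B * (1 - FY) * FX +
    C * FY * (1 - FX) + D * FY * FX
  matrix(vals, target_h, target_w)
}

#' Crop a region of interest from a normalized bounding box
#'
#' Denormalizes a YOLO center-format box (`cx`, `cy`, `w`, `h` relative to
#' image dimensions) to 0-based half-open pixel intervals, rounding half up,
#' and extracts the sub-grid together with its class label.
#'
#' @param image Numeric matrix.
#' @param box List or one-row data frame with fields `region_class`
#'   (`"tumor"` or `"non_tumor"`), `cx`, `cy`, `w`, `h` in `[0, 1]`.
#' @param source_image_id Identifier copied into the patch.
#' @return An object of class `roi_patch` with elements `pixels`,
#'   `region_class`, `source_image_id`.
#' @export
crop_roi <- function(image, box, source_image_id = "img") {
  image <- as.matrix(image)
  cx <- box$cx; cy <- box$cy; bw <- box$w; bh <- box$h
  if (any(!is.finite(c(cx, cy, bw, bh))) || cx < 0 || cx > 1 || cy < 0 ||
      cy > 1 || bw <= 0 || bw > 1 || bh <= 0 || bh > 1)
    stop("invalid argument: bounding box outside the unit square")
  h <- nrow(image); w <- ncol(image)
  rhu <- function(z) floor(z + 0.5)  # round half up
  x0 <- max(0, rhu((cx - bw / 2) * w)); x1 <- min(w, rhu((cx + bw / 2) * w))
  y0 <- max(0, rhu((cy - bh / 2) * h)); y1 <- min(h, rhu((cy + bh / 2) * h))
  if (x1 - x0 < 2 || y1 - y0 < 2)
    stop("degenerate roi: crop smaller than 2x2 pixels")
  structure(list(
    pixels = image[(y0 + 1):y1, (x0 + 1):x1, drop = FALSE],
    region_class = box$region_class,
    source_image_id = source_image_id
  ), class = "roi_patch")
}

#' Flatten a 2-D patch into a 1-D intensity signal
#'
#' Row-major raster scan with top-left origin; the inverse is
#' [unflatten_signal()].
#'
#' @param patch An `roi_patch` or a plain numeric matrix.
#' @return Numeric vector of length `height * width` with attribute `dim2d`.
#' @export
flatten_to_signal <- function(patch) {
  px <- if (inherits(patch, "roi_patch")) patch$pixels else as.matrix(patch)
  out <- as.vector(t(px))  # row-major
  attr(out, "dim2d") <- dim(px)
  attr(out, "order") <- "row-major"
  out
}

#' Rebuild a patch matrix from a row-major signal
#'
#' @param values Numeric vector produced by [flatten_to_signal()].
#' @param dim2d Optional `c(height, width)`; defaults to the stored attribute.
#' @return Numeric matrix.
#' @export
unflatten_signal <- function(values, dim2d = attr(values, "dim2d")) {
  if (is.null(dim2d)) stop("invalid argument: target dimensions unknown")
  matrix(values, nrow = dim2d[1], ncol = dim2d[2], byrow = TRUE)
}

#' Rescale intensities onto the fixed [0, 255] range
#'
#' Histogram-based descriptors in the feature bank assume this range.
#' Constant inputs map to the midpoint 127.5.
#'
#' @param x Numeric matrix or vector.
#' @return Same shape as `x`, values in `[0, 255]`.
#' @export
scale_intensity <- function(x) {
  rng <- range(x)
  if (!all(is.finite(rng))) stop("invalid input: non-finite values")
  if (rng[2] == rng[1]) {
    x[] <- 127.5
    return(x)
  }
  (x - rng[1]) / (rng[2] - rng[1]) * 255
}

#' Standardize an ROI patch for feature extraction
#'
#' Applies the full preprocessing contract: Gaussian denoising of the source
#' image, box cropping, bilinear resizing to the standard square size,
#' intensity rescaling to `[0, 255]`, and row-major rasterization.
#'
#' @param image Numeric matrix (full image).
#' @param box Normalized bounding box (see [crop_roi()]).
#' @param roi_size Standard ROI side length in pixels (default 64).
#' @param sigma Denoising sigma in pixels (default 1).
#' @param source_image_id Identifier carried through to the signal.
#' @return Numeric signal with attributes `region_class`, `source_image_id`.
#' @export
preprocess_roi <- function(image, box, roi_size = 64, sigma = 1,
                           source_image_id = "img") {
  den <- gaussian_denoise(image, sigma)
  patch <- crop_roi(den, box, source_image_id)
  patch$pixels <- scale_intensity(
    bilinear_resize(patch$pixels, roi_size, roi_size))
  sig <- flatten_to_signal(patch)
  attr(sig, "region_class") <- patch$region_class
  attr(sig, "source_image_id") <- patch$source_image_id
  sig
}

#' Read a grayscale PNG or TIFF image as an intensity matrix
#'
#' 8- or 16-bit images are converted to float; multichannel images are
#' averaged to one channel. Values are returned on the native [0, 1] scale
#' of the decoder.
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @return Numeric matrix.
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("invalid argument: unsupported image format '", ext, "'"))
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  as.matrix(img)
}

#' Write an intensity matrix as a grayscale PNG
#'
#' @param image Numeric matrix; rescaled to [0, 1] for encoding.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(image, path) {
  rng <- range(image)
  norm <- if (rng[2] > rng[1]) (image - rng[1]) / (rng[2] - rng[1])
          else matrix(0.5, nrow(image), ncol(image))
  png::writePNG(norm, path)
  invisible(path)
}

#' Read YOLO-format label files
#'
#' One line per box: `class cx cy w h`, whitespace-separated normalized
#' floats; class 0 is tumor, class 1 non-tumor.
#'
#' @param path Label file path.
#' @return Data frame with columns `region_class`, `cx`, `cy`, `w`, `h`.
#' @export
read_yolo_labels <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(data.frame(region_class = character(), cx = numeric(),
                      cy = numeric(), w = numeric(), h = numeric()))
  parts <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  data.frame(
    region_class = ifelse(parts[, 1] == 0, "tumor", "non_tumor"),
    cx = parts[, 2], cy = parts[, 3], w = parts[, 4], h = parts[, 5]
  )
}

#' Write YOLO-format label files
#'
#' @param boxes Data frame as returned by [read_yolo_labels()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_yolo_labels <- function(boxes, path) {
  cls <- ifelse(boxes$region_class == "tumor", 0L, 1L)
  writeLines(sprintf("%d %.6f %.6f %.6f %.6f",
                     cls, boxes$cx, boxes$cy, boxes$w, boxes$h), path)
  invisible(path)
}
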