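#' Configuration of the synthetic MRI-like data generator
#'
#' The generator plants the class structure the entropy bank is designed to
#' detect: tumor regions carry irregular, high-entropy texture (white noise
#' mixed with multiplicative speckle), while background brain tissue is a
#' smooth first-order autoregressive texture on a disk over a dark field.
#'
#' In `"study"` mode every image carries a tumor blob plus a background
#' region and the split is fixed to 583 training / 123 validation / 128
#' test images, so the test split yields a 256-row (128 tumor + 128
#' non-tumor ROIs) classification table; `"quick"` mode uses small counts
#' for fast checks.
#'
#' @param mode `"quick"` or `"study"`.
#' @param image_size Image side in pixels (default 160).
#' @param blob_radius Tumor blob semi-axis range in pixels.
#' @param tumor_noise_sd SD of the tumor white-noise component.
#' @param speckle_weight Mixture weight of the multiplicative speckle.
#' @param ar_coef Background AR(1) coefficient in `(-1, 1)` (default 0.95).
#' @param innovation_sd Background innovation SD.
#' @param n_tumor,n_non_tumor Image counts per class (quick mode).
#' @param split Train/validation/test fractions summing to 1.
#' @param seed Generator seed.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(mode = c("quick", "study"), image_size = 160,
                         blob_radius = c(10, 24), tumor_noise_sd = 1,
                         speckle_weight = 0.5, ar_coef = 0.95,
                         innovation_sd = 1, n_tumor = 20, n_non_tumor = 20,
                         split = c(0.70, 0.15, 0.15), seed = 1L) {
  mode <- match.arg(mode)
  if (abs(sum(split) - 1) > 1e-9) stop("invalid config: split must sum to 1")
  if (ar_coef <= -1 || ar_coef >= 1)
    stop("invalid config: ar_coef must be in (-1, 1)")
  if (max(blob_radius) * 2 >= image_size)
    stop("invalid config: blob larger than image")
  if (n_tumor < 1 || n_non_tumor < 1) stop("invalid config: counts >= 1")
  structure(list(
    mode = mode, image_size = as.integer(image_size),
    blob_radius = blob_radius, tumor_noise_sd = tumor_noise_sd,
    speckle_weight = speckle_weight, ar_coef = ar_coef,
    innovation_sd = innovation_sd,
    n_tumor = as.integer(n_tumor), n_non_tumor = as.integer(n_non_tumor),
    split = split, seed = as.integer(seed)
  ), class = "synth_config")
}

# AR(1) texture rasterized row-major onto an h x w grid
.ar_texture <- function(h, w, coef, sd) {
  n <- h * w
  x <- stats::filter(stats::rnorm(n, 0, sd), coef, method = "recursive")
  matrix(as.numeric(x), h, w, byrow = TRUE)
}

#' Generate one synthetic image with bounding boxes
#'
#' Background: smooth AR(1)-textured elliptical "brain" disk on a dark
#' field. Tumor images additionally contain an elliptical blob of
#' high-variance speckle texture with its enclosing (normalized YOLO
#' center-format) box. Every image yields at least one non-tumor box over
#' background tissue; tumor images yield the tumor box as well, non-tumor
#' images a second background box so a within-image reference region always
#' exists.
#'
#' @param cls `"tumor"` or `"non_tumor"` (image-level class).
#' @param config A [synth_config()]. The caller controls the RNG state.
#' @param image_id Identifier stored with the output.
#' @return List: `image` (matrix in [0, 1] nominal units), `boxes` (data
#'   frame of normalized boxes with `region_class`), `image_id`.
#' @export
generate_image <- function(cls = c("tumor", "non_tumor"),
                           config = synth_config(), image_id = "img") {
  cls <- match.arg(cls)
  s <- config$image_size
  bg <- .ar_texture(s, s, config$ar_coef, config$innovation_sd)
  bg <- (bg - mean(bg)) / (stats::sd(bg) + 1e-12) * 0.08 + 0.55
  yy <- matrix(seq_len(s), s, s); xx <- t(yy)
  cy0 <- s / 2; cx0 <- s / 2
  brain <- ((xx - cx0) / (0.44 * s))^2 + ((yy - cy0) / (0.46 * s))^2 <= 1
  img <- matrix(0.03, s, s) + matrix(stats::runif(s * s, 0, 0.02), s, s)
  img[brain] <- bg[brain]
  rad <- stats::runif(2, config$blob_radius[1], config$blob_radius[2])
  # blob confined to the upper half of the brain disk, background box to
  # the lower half: the vertical gap guarantees disjoint regions
  bc_x <- cx0 + stats::runif(1, -0.22, 0.22) * s
  bc_y <- cy0 - stats::runif(1, 0.10, 0.28) * s
  boxes <- data.frame(region_class = character(), cx = numeric(),
                      cy = numeric(), w = numeric(), h = numeric())
  if (cls == "tumor") {
    blob <- ((xx - bc_x) / rad[1])^2 + ((yy - bc_y) / rad[2])^2 <= 1
    nblob <- sum(blob)
    noise <- stats::rnorm(nblob, 0, config$tumor_noise_sd)
    speck <- stats::rexp(nblob) - 1           # heavy-tailed speckle
    tex <- (1 - config$speckle_weight) * noise + config$speckle_weight * speck
    img[blob] <- 0.6 + 0.18 * tex
    boxes <- rbind(boxes, data.frame(
      region_class = "tumor",
      cx = bc_x / s, cy = bc_y / s,
      w = 2 * (rad[1] + 2) / s, h = 2 * (rad[2] + 2) / s))
  }
  # background boxes on brain tissue in the lower half
  side <- 2 * mean(config$blob_radius)
  bx <- cx0 + stats::runif(1, -0.05, 0.05) * s
  boxes <- rbind(boxes, data.frame(
    region_class = "non_tumor",
    cx = bx / s, cy = (cy0 + 0.22 * s) / s, w = side / s, h = side / s))
  if (cls == "non_tumor") {
    # second background region (upper half) as a within-image reference
    boxes <- rbind(boxes, data.frame(
      region_class = "non_tumor",
      cx = bx / s, cy = (cy0 - 0.22 * s) / s, w = side / s, h = side / s))
  }
  boxes$cx <- pmin(pmax(boxes$cx, boxes$w / 2), 1 - boxes$w / 2)
  boxes$cy <- pmin(pmax(boxes$cy, boxes$h / 2), 1 - boxes$h / 2)
  img <- pmin(pmax(img, 0), 1)
  list(image = img, boxes = boxes, image_id = image_id, class = cls)
}

#' Generate a full synthetic dataset with split manifest
#'
#' Draws the configured number of images per class, then performs a seeded
#' stratified shuffle into train/validation/test subsets before any ROI
#' extraction, so no ROI of one source image can appear in two subsets. In
#' `"study"` mode all 834 images are tumor-bearing (each pairs a tumor and
#' a background region) and the subset sizes are fixed to 583/123/128.
#'
#' @param config A [synth_config()].
#' @return List of class `synth_dataset`: `images` (list), `manifest`
#'   (data frame `image_id`, `class`, `subset`), `config`.
#' @export
generate_dataset <- function(config = synth_config()) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)
  if (config$mode == "study") {
    classes <- rep("tumor", 834)
    sizes <- c(train = 583, validation = 123, test = 128)
  } else {
    classes <- c(rep("tumor", config$n_tumor),
                 rep("non_tumor", config$n_non_tumor))
    sizes <- NULL
  }
  n <- length(classes)
  ids <- sprintf("img%04d", seq_len(n))
  subset <- character(n)
  if (is.null(sizes)) {
    for (cl in unique(classes)) {
      idx <- sample(which(classes == cl))
      nc <- length(idx)
      n_val <- max(1L, round(nc * config$split[2]))
      n_test <- max(1L, round(nc * config$split[3]))
      n_train <- nc - n_val - n_test
      if (n_train < 1L)
        stop("invalid config: counts too small for the requested split")
      subset[idx] <- rep(c("train", "validation", "test"),
                         times = c(n_train, n_val, n_test))
    }
  } else {
    idx <- sample(seq_len(n))
    subset[idx] <- rep(names(sizes), times = sizes)
  }
  images <- vector("list", n)
  for (i in seq_len(n))
    images[[i]] <- generate_image(classes[i], config, image_id = ids[i])
  structure(list(
    images = images,
    manifest = data.frame(image_id = ids, class = classes, subset = subset,
                          stringsAsFactors = FALSE),
    config = config
  ), class = "synth_dataset")
}

#' Generate a primary/reference 1-D signal pair directly
#'
#' Shortcut for entropy and optimizer tests: the primary signal carries the
#' requested class texture (tumor: white noise plus speckle bursts;
#' non-tumor: AR(1) with the configured coefficient) and the reference the
#' opposite-class texture from the same seed stream. Both are rescaled to
#' the standard `[0, 255]` intensity range.
#'
#' @param cls `"tumor"` or `"non_tumor"`.
#' @param length Signal length, `>= 64`.
#' @param config A [synth_config()]. The caller controls the RNG state.
#' @param source_image_id Identifier for the pair.
#' @return A [sample_pair()].
#' @export
generate_signal_pair <- function(cls = c("tumor", "non_tumor"), length = 256,
                                 config = synth_config(),
                                 source_image_id = "sim") {
  cls <- match.arg(cls)
  if (length < 64) stop("invalid argument: length must be >= 64")
  tumor_sig <- function() {
    noise <- stats::rnorm(length, 0, config$tumor_noise_sd)
    speck <- stats::rexp(length) - 1
    (1 - config$speckle_weight) * noise + config$speckle_weight * speck
  }
  ar_sig <- function() {
    as.numeric(stats::filter(stats::rnorm(length, 0, config$innovation_sd),
                             config$ar_coef, method = "recursive"))
  }
  primary <- if (cls == "tumor") tumor_sig() else ar_sig()
  reference <- if (cls == "tumor") ar_sig() else tumor_sig()
  sample_pair(scale_intensity(primary), scale_intensity(reference),
              class_label = cls, source_image_id = source_image_id)
}

#' Extract preprocessed sample pairs from a synthetic dataset
#'
#' For each image in the chosen subsets, every annotated box is
#' preprocessed into a standardized 1-D signal ([preprocess_roi()]); each
#' region becomes one sample pair whose reference is the complementary
#' region of the same image, so cross measures compare tumor against
#' background tissue within a source image.
#'
#' @param dataset A [generate_dataset()] result.
#' @param subsets Character vector of subsets to extract (default all).
#' @param roi_size Standard ROI side (default 64).
#' @param sigma Denoising sigma (default 1).
#' @return List of [sample_pair()] objects.
#' @export
dataset_to_pairs <- function(dataset, subsets = c("train", "validation",
                                                  "test"),
                             roi_size = 64, sigma = 1) {
  keep <- dataset$manifest$subset %in% subsets
  pairs <- list()
  for (i in which(keep)) {
    entry <- dataset$images[[i]]
    boxes <- entry$boxes
    sigs <- lapply(seq_len(nrow(boxes)), function(b)
      preprocess_roi(entry$image * 255, boxes[b, ], roi_size = roi_size,
                     sigma = sigma, source_image_id = entry$image_id))
    for (b in seq_len(nrow(boxes))) {
      refb <- if (nrow(boxes) > 1L) (b %% nrow(boxes)) + 1L else b
      pairs[[length(pairs) + 1L]] <- sample_pair(
        primary = as.numeric(sigs[[b]]),
        reference = as.numeric(sigs[[refb]]),
        class_label = boxes$region_class[b],
        source_image_id = paste0(entry$image_id, "_r", b))
    }
  }
  pairs
}

#' Write a synthetic dataset to disk
#'
#' PNG images, YOLO-format label files and a JSON split manifest, the same
#' external formats the preprocessing stage reads back.
#'
#' @param dataset A [generate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "labels"), recursive = TRUE, showWarnings = FALSE)
  for (entry in dataset$images) {
    png::writePNG(entry$image,
                  file.path(dir, "images", paste0(entry$image_id, ".png")))
    write_yolo_labels(entry$boxes,
                      file.path(dir, "labels", paste0(entry$image_id, ".txt")))
  }
  jsonlite::write_json(dataset$manifest,
                       file.path(dir, "manifest.json"), dataframe = "rows")
  invisible(dir)
}
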