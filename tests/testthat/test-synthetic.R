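test_that("image generation is seeded and yields valid boxes", {
  cfg <- synth_config()
  set.seed(1); a <- generate_image("tumor", cfg)
  set.seed(1); b <- generate_image("tumor", cfg)
  expect_identical(a$image, b$image)
  expect_identical(a$boxes, b$boxes)
  expect_equal(a$boxes$region_class, c("tumor", "non_tumor"))
  expect_equal(generate_image("non_tumor", cfg)$boxes$region_class,
               c("non_tumor", "non_tumor"))
  set.seed(2)
  for (i in 1:200) {
    g <- generate_image(sample(c("tumor", "non_tumor"), 1), cfg)
    bx <- g$boxes
    expect_true(all(bx$cx >= 0 & bx$cx <= 1 & bx$cy >= 0 & bx$cy <= 1))
    expect_true(all(bx$w > 0 & bx$w <= 1 & bx$h > 0 & bx$h <= 1))
    expect_true(all(bx$cx - bx$w / 2 >= -1e-9 & bx$cx + bx$w / 2 <= 1 + 1e-9))
    expect_true(all(bx$cy - bx$h / 2 >= -1e-9 & bx$cy + bx$h / 2 <= 1 + 1e-9))
  }
  expect_error(synth_config(blob_radius = c(90, 100), image_size = 160),
               "invalid")
})

test_that("tumor ROIs carry higher sample entropy than background ROIs", {
  cfg <- synth_config(n_tumor = 25, n_non_tumor = 25, seed = 9)
  ds <- generate_dataset(cfg)
  pairs <- dataset_to_pairs(ds, roi_size = 32)
  se <- vapply(pairs, function(p)
    as.numeric(sample_entropy(p$primary, 2, 0.2 * sd(p$primary))),
    numeric(1))
  cls <- vapply(pairs, `[[`, character(1), "class_label")
  expect_lt(wilcox.test(se[cls == "tumor"], se[cls == "non_tumor"],
                        alternative = "greater")$p.value, 0.01)
})

test_that("dataset splits are disjoint, covering and stratified", {
  cfg <- synth_config(n_tumor = 20, n_non_tumor = 20, seed = 3)
  ds <- generate_dataset(cfg)
  m <- ds$manifest
  expect_equal(nrow(m), 40)
  expect_false(any(duplicated(m$image_id)))
  expect_setequal(unique(m$subset), c("train", "validation", "test"))
  # per-class balance within 1 of the configured ratio in each subset
  for (sub in unique(m$subset)) {
    for (cl in unique(m$class)) {
      got <- sum(m$subset == sub & m$class == cl)
      want <- sum(m$class == cl) *
        c(train = 0.70, validation = 0.15, test = 0.15)[[sub]]
      expect_lte(abs(got - round(want)), 1)
    }
  }
  # reproducible from (config, seed)
  ds2 <- generate_dataset(cfg)
  expect_identical(ds$manifest, ds2$manifest)
  expect_identical(ds$images[[5]]$image, ds2$images[[5]]$image)
})

test_that("study-scale mode reproduces the 583/123/128 structure", {
  cfg <- synth_config(mode = "study", seed = 1)
  ds <- generate_dataset(cfg)
  m <- ds$manifest
  expect_equal(nrow(m), 834)
  expect_equal(sum(m$subset == "train"), 583)
  expect_equal(sum(m$subset == "validation"), 123)
  expect_equal(sum(m$subset == "test"), 128)
  # every image pairs a tumor and a background region
  expect_true(all(vapply(ds$images[1:5], function(g)
    setequal(g$boxes$region_class, c("tumor", "non_tumor")), logical(1))))
})

test_that("no source image contributes ROIs to more than one subset", {
  cfg <- synth_config(n_tumor = 12, n_non_tumor = 12, seed = 4)
  ds <- generate_dataset(cfg)
  seen <- list()
  for (sub in c("train", "validation", "test")) {
    pairs <- dataset_to_pairs(ds, subsets = sub, roi_size = 32)
    src <- unique(sub("_r[0-9]+$", "",
                      vapply(pairs, `[[`, character(1), "source_image_id")))
    seen[[sub]] <- src
  }
  expect_length(intersect(seen$train, seen$test), 0)
  expect_length(intersect(seen$train, seen$validation), 0)
  expect_length(intersect(seen$validation, seen$test), 0)
})

test_that("direct signal pairs are reproducible with the planted textures", {
  cfg <- synth_config()
  set.seed(5); p1 <- generate_signal_pair("tumor", 128, cfg)
  set.seed(5); p2 <- generate_signal_pair("tumor", 128, cfg)
  expect_identical(p1$primary, p2$primary)
  expect_length(p1$primary, 128)
  expect_error(generate_signal_pair("tumor", 32), "invalid")
  # background AR(1) texture is more autocorrelated than tumor texture
  set.seed(6)
  ac1 <- function(x) cor(x[-1], x[-length(x)])
  diffs <- replicate(100, {
    t <- generate_signal_pair("tumor", 128, cfg)
    n <- generate_signal_pair("non_tumor", 128, cfg)
    ac1(n$primary) - ac1(t$primary)
  })
  expect_gt(mean(diffs), 0)
  expect_gt(mean(diffs > 0), 0.9)
})

test_that("datasets serialize to PNG + YOLO + manifest and read back", {
  dir <- withr::local_tempdir()
  cfg <- synth_config(n_tumor = 3, n_non_tumor = 3, seed = 8)
  ds <- generate_dataset(cfg)
  write_dataset(ds, dir)
  expect_length(list.files(file.path(dir, "images"), pattern = "png$"), 6)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(nrow(man), 6)
  lb <- read_yolo_labels(file.path(dir, "labels",
                                   paste0(ds$images[[1]]$image_id, ".txt")))
  expect_equal(lb$region_class, ds$images[[1]]$boxes$region_class)
  img <- read_gray_image(file.path(dir, "images",
                                   paste0(ds$images[[1]]$image_id, ".png")))
  expect_equal(dim(img), c(160, 160))
})
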