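test_that("combine_masks merges paired structures and appends background", {
  h <- 16; w <- 16
  left <- matrix(0, h, w); left[4:10, 2:6] <- 1
  right <- matrix(0, h, w); right[4:10, 10:14] <- 1
  heart <- matrix(0, h, w); heart[9:13, 7:10] <- 1
  lc <- matrix(0, h, w); lc[2, 2:6] <- 1
  rc <- matrix(0, h, w); rc[2, 10:14] <- 1
  ms <- combine_masks(list(left_lung = left, right_lung = right,
                           heart = heart, left_clavicle = lc,
                           right_clavicle = rc))
  expect_named(ms, c("lungs", "heart", "clavicles", "background"))
  # disjoint left/right support: union pixel count is the sum
  expect_identical(sum(ms$lungs), sum(left) + sum(right))
  expect_identical(sum(ms$clavicles), sum(lc) + sum(rc))
  expect_identical(ms$background,
                   1 - pmax(ms$lungs, ms$heart, ms$clavicles))
  # all-empty structures: background is all ones
  empty <- matrix(0, 4, 4)
  ms0 <- combine_masks(list(lungs = empty, heart = empty,
                            clavicles = empty))
  expect_true(all(ms0$background == 1))
  expect_length(ms0, 4)
  expect_error(combine_masks(list(lungs = empty, heart = matrix(0, 3, 3),
                                  clavicles = empty)), "shape")
  expect_error(combine_masks(list(lungs = empty + 0.5, heart = empty,
                                  clavicles = empty)), "binary")
})

test_that("samples survive a save/load round trip", {
  s <- generate_phantom(phantom_spec(64, 64, seed = 21))
  d <- withr::local_tempdir()
  paths <- write_sample(s, d)
  back <- load_sample(paths$image,
                      mask_paths = as.list(paths$masks[c("lungs", "heart",
                                                         "clavicles")]))
  # masks exact, image within the 8-bit quantization step
  expect_identical(back$masks$lungs, s$masks$lungs)
  expect_identical(back$masks$clavicles, s$masks$clavicles)
  expect_identical(back$masks$background, s$masks$background)
  expect_lt(max(abs(back$image - s$image)), 1 / 255)
  expect_identical(back$provenance, "loaded")
  expect_error(load_sample(file.path(d, "nope.png"), paths$masks),
               "not found")
  # dimension mismatch between image and mask is an error
  small <- matrix(0, 32, 32)
  png::writePNG(small, file.path(d, "small.png"))
  expect_error(
    load_sample(paths$image,
                mask_paths = list(lungs = file.path(d, "small.png"),
                                  heart = paths$masks[["heart"]],
                                  clavicles = paths$masks[["clavicles"]])),
    "shape")
})

test_that("loading rescales intensities and binarizes masks", {
  d <- withr::local_tempdir()
  img <- matrix(seq(0, 1, length.out = 64), 8, 8)
  img[1, 1] <- 1                      # full-scale pixel
  png::writePNG(img, file.path(d, "i.png"))
  gray_mask <- matrix(c(0, 1), 8, 8)  # 0 and 255 in 8-bit terms
  png::writePNG(gray_mask, file.path(d, "m.png"))
  empty <- matrix(0, 8, 8)
  png::writePNG(empty, file.path(d, "e.png"))
  s <- load_sample(file.path(d, "i.png"),
                   list(lungs = file.path(d, "m.png"),
                        heart = file.path(d, "e.png"),
                        clavicles = file.path(d, "e.png")))
  expect_equal(max(s$image), 1.0)
  expect_true(all(s$masks$lungs %in% c(0, 1)))
  expect_equal(sum(s$masks$lungs), 32)
})

test_that("preprocessing resizes to the target and keeps masks binary", {
  s <- generate_phantom(phantom_spec(64, 64, seed = 12))
  big <- preprocess_sample(s, 512L)
  expect_identical(dim(big$image), c(512L, 512L))
  for (ch in big$masks) {
    expect_identical(dim(ch), c(512L, 512L))
    expect_true(all(ch %in% c(0, 1)))
  }
  expect_identical(big$masks$background,
                   1 - pmax(big$masks$lungs, big$masks$heart,
                            big$masks$clavicles))
  # identity resize leaves the image untouched
  same <- preprocess_sample(s, 64L)
  expect_identical(same$image, s$image)
  expect_error(preprocess_sample(s, 0), "target_size")
})

test_that("augmentation doubles the dataset with in-range nonzero angles", {
  ds <- tiny_dataset(3, size = 64, seed = 41)
  aug <- augment_dataset(ds, -5, 5, seed = 11)
  expect_length(aug, 6)
  expect_identical(augment_dataset(ds, -5, 5, seed = 11), aug)  # seeded
  rot <- Filter(function(s) !is.null(s$meta$angle), aug)
  expect_length(rot, 3)
  for (s in rot) {
    expect_true(all(unlist(s$masks) %in% c(0, 1)))
    expect_identical(dim(s$image), c(64L, 64L))
    expect_match(s$id, "_rot$")
    expect_false(identical(s$meta$source_id, s$id))
  }
  expect_error(augment_dataset(ds, 2, 5), "degenerate")
})

test_that("augmentation angles stay in range and avoid zero over many seeds", {
  ds <- tiny_dataset(1, size = 32, seed = 50)
  angles <- vapply(1:100, function(seed) {
    aug <- augment_dataset(ds, -5, 5, seed = seed)
    aug[[2]]$meta$angle
  }, numeric(1))
  expect_true(all(angles >= -5 & angles <= 5))
  expect_true(all(angles != 0))
})

test_that("splits are disjoint, exhaustive, sized, and reproducible", {
  ds <- tiny_dataset(100, size = 32, seed = 60)
  sp <- split_dataset(ds, 0.2, seed = 1)
  expect_length(sp$test_ids, 20)
  expect_length(sp$train_ids, 80)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  expect_setequal(c(sp$train_ids, sp$test_ids), dataset_ids(ds))
  expect_identical(split_dataset(ds, 0.2, seed = 1), sp)
  expect_false(identical(split_dataset(ds, 0.2, seed = 2)$test_ids,
                         sp$test_ids))
  # randomized fractions keep the partition property
  for (f in c(0.1, 0.3, 0.5)) {
    spf <- split_dataset(ds, f, seed = 3)
    expect_length(spf$test_ids, round(f * 100))
    expect_setequal(c(spf$train_ids, spf$test_ids), dataset_ids(ds))
  }
  expect_error(split_dataset(ds, 0), "fraction")
  expect_error(split_dataset(ds, 1.2), "fraction")
})

test_that("stratified splits balance strata within one sample", {
  ds <- tiny_dataset(100, size = 32, seed = 61)
  strata <- rep(c("a", "b"), each = 50)
  sp <- split_dataset(ds, 0.2, seed = 5, strata = strata)
  in_test <- dataset_ids(ds) %in% sp$test_ids
  expect_identical(as.vector(table(strata[in_test])), c(10L, 10L))
  expect_error(split_dataset(ds, 0.2, strata = strata[1:10]), "length")
})

test_that("augmented copies stay on the same side as their source", {
  ds <- tiny_dataset(10, size = 32, seed = 62)
  aug <- augment_dataset(ds, seed = 2)
  sp <- split_dataset(aug, 0.2, seed = 3)
  src <- vapply(aug, function(s) s$meta$source_id, character(1))
  side <- ifelse(dataset_ids(aug) %in% sp$test_ids, "test", "train")
  expect_true(all(tapply(side, src, function(v) length(unique(v))) == 1))
})

test_that("clavicle-fraction strata are valid labels shared with copies", {
  ds <- tiny_dataset(12, size = 48, seed = 63)
  st <- stratify_by_class_fraction(ds, bins = 3)
  expect_length(st, 12)
  expect_true(all(st %in% 1:3))
  aug <- augment_dataset(ds, seed = 4)
  st2 <- stratify_by_class_fraction(aug, bins = 3)
  src <- vapply(aug, function(s) s$meta$source_id, character(1))
  expect_true(all(tapply(st2, src, function(v) length(unique(v))) == 1))
})

test_that("manifest and split files round-trip", {
  ds <- tiny_dataset(4, size = 32, seed = 64)
  d <- withr::local_tempdir()
  for (s in ds) write_sample(s, d)
  write_manifest(ds, d, strata = c(1, 1, 2, 2))
  back <- load_manifest(d)
  expect_identical(dataset_ids(back), dataset_ids(ds))
  expect_identical(attr(back, "strata"), c(1L, 1L, 2L, 2L))
  expect_identical(back[[2]]$masks$lungs, ds[[2]]$masks$lungs)
  sp <- split_dataset(ds, 0.25, seed = 9)
  f <- file.path(d, "split.json")
  write_split(sp, f)
  expect_identical(read_split(f), sp)
})
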