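# Loading, mask combination, preprocessing, augmentation, splitting.
#
# Conventions: rasters are numeric matrices, row-major with origin at the
# top-left; intensities live in [0,1]; mask channels are exactly 0/1.

#' Build a mask stack with a background channel
#'
#' @param channels Named list of binary matrices for the structure classes
#'   (`lungs`, `heart`, `clavicles`), all of one shape. A `background`
#'   channel, if supplied, is ignored and recomputed.
#' @return Object of class `mask_stack`: named list of binary matrices in
#'   canonical order (lungs, heart, clavicles, background), where background
#'   is exactly `1 - pmax(lungs, heart, clavicles)`.
#' @export
mask_stack <- function(channels) {
  channels <- channels[setdiff(names(channels), "background")]
  missing <- setdiff(STRUCTURE_CLASSES, names(channels))
  if (length(missing))
    stop("missing mask channels: ", paste(missing, collapse = ", "),
         call. = FALSE)
  channels <- channels[STRUCTURE_CLASSES]
  ref <- channels[[1L]]
  for (cls in STRUCTURE_CLASSES) {
    ch <- channels[[cls]]
    if (!is_binary_raster(ch))
      stop(sprintf("mask channel '%s' must be a binary matrix", cls),
           call. = FALSE)
    assert_same_shape(ref, ch, "mask channels")
  }
  channels$background <-
    1 - pmax(channels$lungs, channels$heart, channels$clavicles)
  structure(channels, class = "mask_stack")
}

#' @export
print.mask_stack <- function(x, ...) {
  px <- vapply(x, sum, numeric(1))
  cat(sprintf("<mask_stack> %dx%d; pixels: %s\n",
              nrow(x[[1]]), ncol(x[[1]]),
              paste(sprintf("%s=%d", names(px), as.integer(px)),
                    collapse = ", ")))
  invisible(x)
}

#' Combine per-structure masks into a canonical stack
#'
#' Left/right lung rasters are merged by elementwise maximum into one lungs
#' channel, paired clavicle rasters likewise; a background channel is
#' appended as the complement of the union of the structure channels.
#'
#' @param structure_masks Named list of binary matrices. Accepted names:
#'   `left_lung`/`right_lung` (or a single `lungs`), `heart`,
#'   `left_clavicle`/`right_clavicle` (or a single `clavicles`).
#' @return A [mask_stack()] with four channels.
#' @export
combine_masks <- function(structure_masks) {
  nm <- names(structure_masks)
  if (is.null(nm)) stop("structure_masks must be named", call. = FALSE)
  ref <- structure_masks[[1L]]
  for (i in seq_along(structure_masks)) {
    if (!is_binary_raster(structure_masks[[i]]))
      stop(sprintf("mask '%s' must be a binary matrix", nm[i]), call. = FALSE)
    assert_same_shape(ref, structure_masks[[i]], "masks")
  }
  merge_pair <- function(single, left, right) {
    if (single %in% nm) return(structure_masks[[single]])
    parts <- intersect(c(left, right), nm)
    if (!length(parts))
      stop(sprintf("no mask found for class '%s'", single), call. = FALSE)
    Reduce(pmax, structure_masks[parts])
  }
  mask_stack(list(
    lungs = merge_pair("lungs", "left_lung", "right_lung"),
    heart = merge_pair("heart", "heart", "heart"),
    clavicles = merge_pair("clavicles", "left_clavicle", "right_clavicle")))
}

read_raster <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
              png = png::readPNG(path),
              tif = ,
              tiff = tiff::readTIFF(path),
              stop("unreadable format: .", ext, call. = FALSE))
  if (length(dim(x)) == 3L) x <- x[, , 1L]  # first channel of multi-channel
  x
}

#' Load an image and its per-class masks from disk
#'
#' Image intensities are rescaled from the native bit depth to `[0,1]` (the
#' PNG/TIFF readers already emit that range); masks are binarized at 0.5 of
#' full scale and combined into a canonical stack via [combine_masks()].
#'
#' @param image_path Path to a PNG or TIFF grayscale image.
#' @param mask_paths Named character vector/list mapping class names (see
#'   [combine_masks()]) to mask raster paths.
#' @param id Sample identifier; defaults to the image file stem.
#' @return A `sample_pair` with `provenance = "loaded"`.
#' @export
load_sample <- function(image_path, mask_paths,
                        id = tools::file_path_sans_ext(basename(image_path))) {
  image <- read_raster(image_path)
  masks <- lapply(mask_paths, function(p) {
    m <- read_raster(p)
    assert_same_shape(image, m, "image and mask")
    (m >= 0.5) * 1
  })
  names(masks) <- names(mask_paths)
  new_sample_pair(image = image, masks = combine_masks(masks), id = id,
                  provenance = "loaded")
}

#' Resize and normalize a sample
#'
#' The image is resized with bilinear interpolation and renormalized into
#' `[0,1]`; masks are resized with nearest-neighbor interpolation so they
#' stay binary, and the background-complement identity is re-enforced after
#' the resize.
#'
#' @param sample A `sample_pair`.
#' @param target_size Output side length in pixels (square output).
#' @return The resized `sample_pair`.
#' @export
preprocess_sample <- function(sample, target_size = 512L) {
  stop_if_not_scalar_number(target_size, "target_size", min = 1,
                            integer = TRUE)
  img <- sample$image
  if (!identical(dim(img), c(target_size, target_size))) {
    img <- as.matrix(EBImage::resize(img, w = target_size, h = target_size,
                                     filter = "bilinear"))
    resized <- lapply(sample$masks[STRUCTURE_CLASSES], function(m)
      as.matrix(EBImage::resize(m, w = target_size, h = target_size,
                                filter = "none")))
    sample$masks <- mask_stack(resized)
  }
  img <- pmin(pmax(img, 0), 1)
  sample$image <- img
  sample
}

rotate_raster <- function(x, angle, filter) {
  out <- EBImage::rotate(x, angle, filter = filter,
                         output.dim = c(nrow(x), ncol(x)), bg.col = 0)
  as.matrix(out)
}

#' Augment a dataset with one random rotation per sample
#'
#' Returns the original samples plus exactly one rotated copy of each. The
#' rotation angle is drawn uniformly from `[angle_low, angle_high]` with
#' exact zeros re-drawn, the image is rotated bilinearly and the masks with
#' nearest-neighbor about the image center, and the frame size is preserved
#' (corners uncovered by the rotation are filled with 0). Rotated copies get
#' the suffix `_rot` and keep `meta$source_id` pointing at their source, so
#' splits can keep a sample and its copy on one side.
#'
#' @param dataset A `cxr_dataset`.
#' @param angle_low,angle_high Angle range in degrees, `angle_low < 0 <
#'   angle_high`.
#' @param seed Integer seed making the drawn angles reproducible.
#' @return A `cxr_dataset` of size `2 * length(dataset)`.
#' @export
augment_dataset <- function(dataset, angle_low = -5, angle_high = 5,
                            seed = 1L) {
  if (!(angle_low < 0 && 0 < angle_high))
    stop("degenerate angle range: need angle_low < 0 < angle_high",
         call. = FALSE)
  n <- length(dataset)
  angles <- with_seed(seed, {
    a <- stats::runif(n, angle_low, angle_high)
    while (any(a == 0)) a[a == 0] <- stats::runif(sum(a == 0), angle_low,
                                                  angle_high)
    a
  })
  augmented <- vector("list", n)
  for (i in seq_len(n)) {
    s <- dataset[[i]]
    img <- rotate_raster(s$image, angles[i], filter = "bilinear")
    img <- pmin(pmax(img, 0), 1)
    msk <- lapply(s$masks[STRUCTURE_CLASSES], rotate_raster,
                  angle = angles[i], filter = "none")
    augmented[[i]] <- new_sample_pair(
      image = img, masks = mask_stack(msk),
      id = paste0(s$id, "_rot"), provenance = s$provenance,
      meta = utils::modifyList(s$meta,
                               list(source_id = s$id, angle = angles[i])))
  }
  new_dataset(c(unclass(dataset), augmented))
}

#' Split a dataset into train and test sets
#'
#' Produces a disjoint, exhaustive split with `round(test_fraction * n)`
#' test samples. Augmented copies are grouped with their source sample
#' (`meta$source_id`) and always land on the same side, guarding against
#' train/test leakage. With `strata`, test counts are allocated per stratum
#' by largest remainder, so each stratum's test share deviates from
#' `test_fraction` by at most one sample.
#'
#' @param dataset A `cxr_dataset`.
#' @param test_fraction Test share in `(0,1)`.
#' @param seed Integer seed; the same seed reproduces the split.
#' @param strata Optional vector of stratum labels, one per sample (dataset
#'   order). Copies of one source sample must carry its label.
#' @return Object of class `split_result`: list with `train_ids`,
#'   `test_ids`, `seed`, `fraction`.
#' @export
split_dataset <- function(dataset, test_fraction = 0.2, seed = 1L,
                          strata = NULL) {
  if (!(test_fraction > 0 && test_fraction < 1))
    stop("test_fraction must lie in (0,1)", call. = FALSE)
  ids <- dataset_ids(dataset)
  source_ids <- vapply(dataset, function(s)
    if (!is.null(s$meta$source_id)) s$meta$source_id else s$id, character(1))
  if (!is.null(strata)) {
    if (length(strata) != length(ids))
      stop("strata length must match the dataset size", call. = FALSE)
    # a source group must sit in a single stratum
    gs <- tapply(as.character(strata), source_ids,
                 function(v) length(unique(v)))
    if (any(gs > 1))
      stop("augmented copies must share their source sample's stratum",
           call. = FALSE)
    group_strata <- tapply(as.character(strata), source_ids, `[`, 1L)
  } else {
    group_strata <- tapply(rep("all", length(ids)), source_ids, `[`, 1L)
  }
  groups <- split(ids, source_ids)
  group_names <- names(groups)
  group_sizes <- lengths(groups)
  n_total <- length(ids)
  n_test_target <- round(test_fraction * n_total)

  with_seed(seed, {
    test_groups <- character(0)
    # largest-remainder allocation of test counts across strata
    strata_levels <- unique(group_strata[group_names])
    exact <- vapply(strata_levels, function(sl) {
      test_fraction * sum(group_sizes[group_strata[group_names] == sl])
    }, numeric(1))
    base_n <- floor(exact)
    leftover <- n_test_target - sum(base_n)
    if (leftover > 0) {
      order_rem <- order(exact - base_n, decreasing = TRUE)
      bump <- order_rem[seq_len(min(leftover, length(strata_levels)))]
      base_n[bump] <- base_n[bump] + 1
    } else if (leftover < 0) {
      order_rem <- order(exact - base_n)
      drop <- order_rem[seq_len(min(-leftover, length(strata_levels)))]
      base_n[drop] <- pmax(base_n[drop] - 1, 0)
    }
    for (k in seq_along(strata_levels)) {
      sl <- strata_levels[k]
      g <- group_names[group_strata[group_names] == sl]
      g <- sample(g)
      want <- base_n[k]
      got <- 0; pick <- character(0)
      for (gn in g) {
        if (got >= want) break
        pick <- c(pick, gn)
        got <- got + group_sizes[gn]
      }
      test_groups <- c(test_groups, pick)
    }
    test_ids <- ids[ids %in% unlist(groups[test_groups], use.names = FALSE)]
    train_ids <- setdiff(ids, test_ids)
    structure(list(train_ids = train_ids, test_ids = test_ids,
                   seed = as.integer(seed), fraction = test_fraction),
              class = "split_result")
  })
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("<split_result> %d train / %d test (fraction %.2f, seed %d)\n",
              length(x$train_ids), length(x$test_ids), x$fraction, x$seed))
  invisible(x)
}

#' Write a split to JSON
#' @param split A `split_result`.
#' @param path Output path.
#' @export
write_split <- function(split, path) {
  jsonlite::write_json(unclass(split), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a split from JSON
#' @param path JSON file written by [write_split()].
#' @export
read_split <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(train_ids = as.character(x$train_ids),
                 test_ids = as.character(x$test_ids),
                 seed = as.integer(x$seed), fraction = x$fraction),
            class = "split_result")
}

#' Stratification labels from the clavicle pixel fraction
#'
#' The segmentation classes are present in every image, so stratification
#' needs a per-image scalar; the fraction of pixels in the rarest class
#' (clavicles) is the one a split should balance. Labels are quantile bins
#' of that fraction.
#'
#' @param dataset A `cxr_dataset`.
#' @param bins Number of quantile bins.
#' @param class Mask channel to bin on (default `"clavicles"`).
#' @return Integer vector of stratum labels (1..bins), one per sample.
#' @export
stratify_by_class_fraction <- function(dataset, bins = 2L,
                                       class = "clavicles") {
  frac <- vapply(dataset, function(s) mean(s$masks[[class]]), numeric(1))
  # bin on the source sample's fraction so copies share their source stratum
  src <- vapply(dataset, function(s)
    if (!is.null(s$meta$source_id)) s$meta$source_id else s$id, character(1))
  frac_by_src <- tapply(frac, src, `[`, 1L)
  base_frac <- as.numeric(frac_by_src[src])
  qs <- stats::quantile(unique(frac_by_src),
                        probs = seq(0, 1, length.out = bins + 1L))
  labs <- findInterval(base_frac, qs, rightmost.closed = TRUE,
                       all.inside = TRUE)
  as.integer(labs)
}

#' Write a dataset manifest CSV
#'
#' Columns: `id`, `image`, one mask-path column per structure class, and
#' optionally `stratum`.
#'
#' @param dataset A `cxr_dataset` already written by [write_sample()].
#' @param dir Dataset root containing `images/` and `masks/`.
#' @param strata Optional stratum labels, one per sample.
#' @return Path to `dir/manifest.csv`, invisibly.
#' @export
write_manifest <- function(dataset, dir, strata = NULL) {
  ids <- dataset_ids(dataset)
  df <- data.frame(id = ids,
                   image = file.path("images", paste0(ids, ".png")),
                   lungs = file.path("masks", paste0(ids, "_lungs.png")),
                   heart = file.path("masks", paste0(ids, "_heart.png")),
                   clavicles = file.path("masks",
                                         paste0(ids, "_clavicles.png")),
                   stringsAsFactors = FALSE)
  if (!is.null(strata)) df$stratum <- strata
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Load a dataset from a manifest CSV
#'
#' @param dir Dataset root holding `manifest.csv` (paths in the manifest are
#'   relative to `dir`).
#' @return A `cxr_dataset`; any `stratum` column is attached as
#'   `attr(, "strata")`.
#' @export
load_manifest <- function(dir) {
  path <- file.path(dir, "manifest.csv")
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  samples <- lapply(seq_len(nrow(df)), function(i) {
    load_sample(file.path(dir, df$image[i]),
                mask_paths = list(lungs = file.path(dir, df$lungs[i]),
                                  heart = file.path(dir, df$heart[i]),
                                  clavicles = file.path(dir, df$clavicles[i])),
                id = df$id[i])
  })
  out <- new_dataset(samples)
  if ("stratum" %in% names(df)) attr(out, "strata") <- df$stratum
  out
}
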