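# Synthetic chest phantom generator.
#
# Phantoms emulate the statistical layout of an adult posteroanterior chest
# radiograph at the level needed to exercise a segmentation pipeline: two
# large bright lung fields, one medium cardiac silhouette overlapping a lung,
# two thin low-contrast clavicle bars crossing the upper lung zone, heavy
# class imbalance (lungs >> heart >> clavicles by pixel count), additive
# noise, and soft boundary contrast. They are not anatomically realistic
# radiograph simulations; they carry exactly known ground truth.

#' Specification of a synthetic chest phantom
#'
#' @param height,width Image size in pixels (each at least 32).
#' @param contrast Structure-to-background intensity gap on the `[0,1]`
#'   intensity scale, in `(0, 1]`. Clavicle bars are drawn at half this
#'   contrast, making them the hardest, lowest-contrast class.
#' @param noise_sd Standard deviation of additive Gaussian noise applied on
#'   the `[0,1]` scale (the image is clipped back to `[0,1]`); must be >= 0.
#' @param seed Integer seed; identical specs produce bit-identical phantoms.
#'
#' @return An object of class `phantom_spec`.
#' @export
#' @examples
#' spec <- phantom_spec(height = 64, width = 64, seed = 7)
#' sp <- generate_phantom(spec)
#' dim(sp$image)
phantom_spec <- function(height = 128L, width = 128L, contrast = 0.5,
                         noise_sd = 0.03, seed = 1L) {
  stop_if_not_scalar_number(height, "height", min = 32, integer = TRUE)
  stop_if_not_scalar_number(width, "width", min = 32, integer = TRUE)
  stop_if_not_scalar_number(contrast, "contrast", min = 0, max = 1,
                            strict_min = TRUE)
  stop_if_not_scalar_number(noise_sd, "noise_sd", min = 0)
  stop_if_not_scalar_number(seed, "seed", integer = TRUE)
  structure(list(height = as.integer(height), width = as.integer(width),
                 contrast = contrast, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %dx%d, contrast %.3g, noise_sd %.3g, seed %d\n",
              x$height, x$width, x$contrast, x$noise_sd, x$seed))
  invisible(x)
}

# Filled-ellipse mask on a pixel grid (0-based centers in pixel units).
ellipse_mask <- function(h, w, cx, cy, ax, ay, angle = 0) {
  xs <- matrix(rep(seq_len(w) - 1, each = h), h, w)
  ys <- matrix(rep(seq_len(h) - 1, times = w), h, w)
  ca <- cos(angle); sa <- sin(angle)
  xr <- (xs - cx) * ca + (ys - cy) * sa
  yr <- -(xs - cx) * sa + (ys - cy) * ca
  m <- (xr / ax)^2 + (yr / ay)^2 <= 1
  storage.mode(m) <- "double"
  m
}

# Filled rotated bar (rectangle) mask; length along the bar axis, thickness
# across it, rotated by `angle` radians about (cx, cy).
bar_mask <- function(h, w, cx, cy, len, thick, angle) {
  xs <- matrix(rep(seq_len(w) - 1, each = h), h, w)
  ys <- matrix(rep(seq_len(h) - 1, times = w), h, w)
  ca <- cos(angle); sa <- sin(angle)
  xr <- (xs - cx) * ca + (ys - cy) * sa
  yr <- -(xs - cx) * sa + (ys - cy) * ca
  m <- abs(xr) <= len / 2 & abs(yr) <= thick / 2
  storage.mode(m) <- "double"
  m
}

#' Generate one synthetic chest phantom
#'
#' Draws two large lung ellipses offset from the background by
#' `spec$contrast`, a medium heart ellipse partially overlapping the right
#' lung, and two thin rotated clavicle bars crossing the upper lung region at
#' half contrast. Centers, axes, and angles receive mild seeded jitter so a
#' dataset of phantoms has inter-sample variability for augmentation and
#' stratification to exercise. Ground-truth masks contain the exact geometry;
#' the background channel is the exact complement of the union of the three
#' structure channels.
#'
#' @param spec A [phantom_spec()].
#' @return A `sample_pair`: list with `image` (matrix in `[0,1]`), `masks`
#'   (a [mask_stack()] with channels lungs, heart, clavicles, background),
#'   `id`, `provenance = "synthetic"`, and `meta` (including `source_id`).
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  h <- spec$height; w <- spec$width
  with_seed(spec$seed, {
    jit <- function(scale) stats::runif(1, -scale, scale)

    # lungs: two tall ellipses, mirrored about the midline
    lungs <- pmax(
      ellipse_mask(h, w,
                   cx = (0.30 + jit(0.02)) * w, cy = (0.46 + jit(0.02)) * h,
                   ax = (0.155 + jit(0.012)) * w, ay = (0.29 + jit(0.02)) * h,
                   angle = jit(0.06)),
      ellipse_mask(h, w,
                   cx = (0.70 + jit(0.02)) * w, cy = (0.46 + jit(0.02)) * h,
                   ax = (0.155 + jit(0.012)) * w, ay = (0.29 + jit(0.02)) * h,
                   angle = jit(0.06)))

    # heart: medium ellipse low and central, overlapping the right lung field
    heart <- ellipse_mask(h, w,
                          cx = (0.555 + jit(0.02)) * w,
                          cy = (0.625 + jit(0.02)) * h,
                          ax = (0.135 + jit(0.01)) * w,
                          ay = (0.155 + jit(0.01)) * h,
                          angle = 0.2 + jit(0.08))

    # clavicles: thin bars crossing the upper lung zones, tilted a few degrees
    clav <- pmax(
      bar_mask(h, w, cx = (0.30 + jit(0.015)) * w, cy = (0.20 + jit(0.01)) * h,
               len = (0.34 + jit(0.02)) * w, thick = max(2, 0.022 * h),
               angle = 0.18 + jit(0.05)),
      bar_mask(h, w, cx = (0.70 + jit(0.015)) * w, cy = (0.20 + jit(0.01)) * h,
               len = (0.34 + jit(0.02)) * w, thick = max(2, 0.022 * h),
               angle = -0.18 + jit(0.05)))

    base <- 0.25
    img <- matrix(base, h, w)
    img[lungs == 1] <- base + spec$contrast * 0.9
    img[heart == 1] <- base + spec$contrast * 0.6
    # clavicle bars are drawn at half the lung offset, so they sit at low
    # contrast against both the background and the lung fields they cross
    img[clav == 1] <- base + spec$contrast * 0.45

    if (spec$noise_sd > 0)
      img <- img + matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w)
    img <- pmin(pmax(img, 0), 1)

    masks <- mask_stack(list(lungs = lungs, heart = heart, clavicles = clav))
    new_sample_pair(image = img, masks = masks,
                    id = sprintf("phantom_%08d", spec$seed %% 100000000L),
                    provenance = "synthetic",
                    meta = list(spec = unclass(spec)))
  })
}

new_sample_pair <- function(image, masks, id, provenance,
                            meta = list()) {
  if (is.null(meta$source_id)) meta$source_id <- id
  structure(list(image = image, masks = masks, id = id,
                 provenance = provenance, meta = meta),
            class = "sample_pair")
}

#' @export
print.sample_pair <- function(x, ...) {
  cat(sprintf("<sample_pair> '%s' (%s), %dx%d, %d mask channels\n",
              x$id, x$provenance, nrow(x$image), ncol(x$image),
              length(x$masks)))
  invisible(x)
}

#' Generate a dataset of phantoms
#'
#' Per-sample seeds are derived deterministically from `base_spec$seed` and
#' the sample index, so the same call always reproduces the same dataset.
#'
#' @param n Number of phantoms (>= 1).
#' @param base_spec A [phantom_spec()] providing geometry/noise parameters
#'   and the base seed.
#' @return A `cxr_dataset` (ordered list of `sample_pair`s with unique ids).
#' @export
generate_dataset <- function(n, base_spec = phantom_spec()) {
  stop_if_not_scalar_number(n, "n", min = 1, integer = TRUE)
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    seed_i <- as.integer(derive_seed(base_spec$seed, i))
    sp <- base_spec
    sp$seed <- seed_i
    s <- generate_phantom(sp)
    s$id <- sprintf("phantom_%05d", i)
    s$meta$source_id <- s$id
    s$meta$index <- i
    samples[[i]] <- s
  }
  new_dataset(samples)
}

new_dataset <- function(samples) {
  ids <- vapply(samples, function(s) s$id, character(1))
  if (anyDuplicated(ids)) stop("sample identifiers must be unique", call. = FALSE)
  names(samples) <- ids
  structure(samples, class = "cxr_dataset")
}

#' @export
print.cxr_dataset <- function(x, ...) {
  cat(sprintf("<cxr_dataset> %d samples\n", length(x)))
  invisible(x)
}

#' @export
`[.cxr_dataset` <- function(x, i) {
  new_dataset(unclass(x)[i])
}

#' Dataset identifiers
#' @param dataset A `cxr_dataset`.
#' @return Character vector of sample ids, in dataset order.
#' @export
dataset_ids <- function(dataset) {
  unname(vapply(dataset, function(s) s$id, character(1)))
}

#' Write a sample to disk
#'
#' Emits the image as 8-bit PNG (or 16-bit TIFF), one binary PNG per mask
#' class named `<id>_<class>.png`, and a JSON sidecar with the generating
#' spec / metadata.
#'
#' @param sample A `sample_pair`.
#' @param dir Output directory (created if absent); images go to
#'   `dir/images`, masks to `dir/masks`.
#' @param format `"png"` (8-bit) or `"tiff"` (16-bit).
#' @return Invisibly, a named list of the written paths.
#' @export
write_sample <- function(sample, dir, format = c("png", "tiff")) {
  format <- match.arg(format)
  img_dir <- file.path(dir, "images"); msk_dir <- file.path(dir, "masks")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(msk_dir, recursive = TRUE, showWarnings = FALSE)
  if (format == "png") {
    image_path <- file.path(img_dir, paste0(sample$id, ".png"))
    png::writePNG(sample$image, image_path)
  } else {
    image_path <- file.path(img_dir, paste0(sample$id, ".tif"))
    tiff::writeTIFF(sample$image, image_path, bits.per.sample = 16L)
  }
  mask_paths <- character(0)
  for (cls in names(sample$masks)) {
    p <- file.path(msk_dir, sprintf("%s_%s.png", sample$id, cls))
    png::writePNG(sample$masks[[cls]], p)
    mask_paths[cls] <- p
  }
  sidecar <- file.path(img_dir, paste0(sample$id, ".json"))
  jsonlite::write_json(
    list(id = sample$id, provenance = sample$provenance, meta = sample$meta),
    sidecar, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(image = image_path, masks = mask_paths, sidecar = sidecar))
}
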