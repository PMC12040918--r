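# Gradient-based edge detection and artifact-suppression operators.
#
# The gradient at pixel (i, j) is computed by correlating the image with a
# 3x3 kernel pair:
#
#   gx(i,j) = sum_{u=-1..1} sum_{v=-1..1} I(i+u, j+v) * kx(u+2, v+2)
#   gy(i,j) = likewise with ky
#   g(i,j)  = sqrt(gx^2 + gy^2)
#
# i.e. the correlation (no kernel flip) form of the printed double sums.

#' Sobel kernel pair
#'
#' Standard Sobel horizontal/vertical gradient kernels. `gx` responds to
#' intensity changes across columns, `gy` across rows; both sum to zero.
#'
#' @return List with 3x3 matrices `gx` and `gy`.
#' @export
sobel_kernels <- function() {
  gx <- matrix(c(-1, 0, 1,
                 -2, 0, 2,
                 -1, 0, 1), 3, 3, byrow = TRUE)
  gy <- matrix(c(-1, -2, -1,
                  0,  0,  0,
                  1,  2,  1), 3, 3, byrow = TRUE)
  list(gx = gx, gy = gy)
}

#' Scharr kernel pair
#'
#' Scharr gradient kernels with +/-10 center weights, which give better
#' rotational symmetry than Sobel:
#' `gx` rows (-3, 0, 3), (-10, 0, 10), (-3, 0, 3);
#' `gy` rows (-3, -10, -3), (0, 0, 0), (3, 10, 3).
#'
#' @return List with 3x3 matrices `gx` and `gy`.
#' @export
scharr_kernels <- function() {
  gx <- matrix(c(-3,  0,  3,
                 -10, 0, 10,
                 -3,  0,  3), 3, 3, byrow = TRUE)
  gy <- matrix(c(-3, -10, -3,
                  0,   0,  0,
                  3,  10,  3), 3, 3, byrow = TRUE)
  list(gx = gx, gy = gy)
}

# Pad a matrix by one pixel under a named border rule. `reflect` mirrors
# without repeating the edge row/column (index 0 -> 2); `replicate` clamps.
pad1 <- function(image, border) {
  h <- nrow(image); w <- ncol(image)
  ri <- switch(border,
               replicate = c(1L, seq_len(h), h),
               reflect   = c(2L, seq_len(h), h - 1L),
               zero      = c(NA, seq_len(h), NA))
  ci <- switch(border,
               replicate = c(1L, seq_len(w), w),
               reflect   = c(2L, seq_len(w), w - 1L),
               zero      = c(NA, seq_len(w), NA))
  if (border == "zero") {
    out <- matrix(0, h + 2L, w + 2L)
    out[2:(h + 1L), 2:(w + 1L)] <- image
    out
  } else {
    image[ri, ci]
  }
}

#' 3x3 correlation of a grayscale image
#'
#' Evaluates `out(i,j) = sum_u sum_v I(i+u, j+v) * k(u+2, v+2)` for
#' `u, v in -1..1` (correlation; the kernel is not flipped). The output has
#' the input's shape; out-of-range pixels at the border are supplied by the
#' chosen border rule.
#'
#' @param image Numeric matrix, at least 3x3.
#' @param kernel 3x3 numeric matrix with finite coefficients.
#' @param border One of `"replicate"` (clamp to edge), `"reflect"` (mirror,
#'   edge not repeated), `"zero"`.
#' @return Numeric matrix with `dim(image)`.
#' @export
#' @examples
#' img <- matrix(runif(25), 5, 5)
#' identity_k <- matrix(c(0, 0, 0, 0, 1, 0, 0, 0, 0), 3, 3)
#' all.equal(convolve3x3(img, identity_k), img)
convolve3x3 <- function(image, kernel,
                        border = c("replicate", "reflect", "zero")) {
  border <- match.arg(border)
  assert_gray_image(image)
  if (nrow(image) < 3L || ncol(image) < 3L)
    stop("image must be at least 3x3", call. = FALSE)
  if (!is.matrix(kernel) || !identical(dim(kernel), c(3L, 3L)) ||
      !all(is.finite(kernel)))
    stop("kernel must be a 3x3 matrix of finite coefficients", call. = FALSE)
  h <- nrow(image); w <- ncol(image)
  p <- pad1(image, border)
  out <- matrix(0, h, w)
  # nine shifted, weighted adds: u/v are the -1..1 offsets of the sums
  for (u in -1:1) for (v in -1:1) {
    k <- kernel[u + 2L, v + 2L]
    if (k != 0)
      out <- out + k * p[(2L + u):(h + 1L + u), (2L + v):(w + 1L + v)]
  }
  out
}

#' Total gradient magnitude
#'
#' Elementwise `sqrt(gx^2 + gy^2)`.
#'
#' @param gx,gy Gradient responses of identical shape.
#' @return Nonnegative matrix of the same shape.
#' @export
gradient_magnitude <- function(gx, gy) {
  assert_gray_image(gx, "gx"); assert_gray_image(gy, "gy")
  assert_same_shape(gx, gy, "gx and gy")
  sqrt(gx^2 + gy^2)
}

#' Gradient field of an image
#'
#' Applies the Sobel or Scharr kernel pair by [convolve3x3()] and combines
#' the axis responses into the total gradient magnitude.
#'
#' @inheritParams convolve3x3
#' @param method `"sobel"` or `"scharr"`.
#' @return Object of class `gradient_field`: list with `gx`, `gy`,
#'   `magnitude`, and `method`.
#' @export
edge_map <- function(image, method = c("sobel", "scharr"),
                     border = c("replicate", "reflect", "zero")) {
  method <- match.arg(method)
  border <- match.arg(border)
  ks <- switch(method, sobel = sobel_kernels(), scharr = scharr_kernels())
  gx <- convolve3x3(image, ks$gx, border)
  gy <- convolve3x3(image, ks$gy, border)
  structure(list(gx = gx, gy = gy,
                 magnitude = gradient_magnitude(gx, gy),
                 method = method),
            class = "gradient_field")
}

#' @export
print.gradient_field <- function(x, ...) {
  cat(sprintf("<gradient_field> %s, %dx%d, max |g| = %.4g\n", x$method,
              nrow(x$magnitude), ncol(x$magnitude), max(x$magnitude)))
  invisible(x)
}

#' Contrast-limited adaptive histogram equalization
#'
#' The image is divided into a `tiles` x `tiles` grid. Each tile's 256-bin
#' histogram is clipped at `clip` times the uniform bin level (tile pixels /
#' bins), the clipped excess is redistributed uniformly over all bins, and
#' the tile mapping is the resulting cumulative distribution. Each output
#' pixel blends the mappings of its four neighboring tile centers bilinearly,
#' so tile seams are invisible. With `tiles = 1` and a clip level that never
#' binds this reduces exactly to global histogram equalization.
#'
#' @param image Numeric matrix with intensities in `[0,1]`.
#' @param clip Clip limit as a multiple of the uniform histogram level; > 0.
#' @param tiles Tiles per axis (integer >= 1).
#' @param bins Number of histogram bins (default 256).
#' @return Matrix in `[0,1]` with the input's shape.
#' @export
clahe <- function(image, clip = 2, tiles = 8L, bins = 256L) {
  assert_gray_image(image)
  if (min(image) < 0 || max(image) > 1)
    stop("image intensities must lie in [0,1]", call. = FALSE)
  stop_if_not_scalar_number(clip, "clip", min = 0, strict_min = TRUE)
  stop_if_not_scalar_number(tiles, "tiles", min = 1, integer = TRUE)
  h <- nrow(image); w <- ncol(image)
  tiles <- as.integer(min(tiles, h, w))
  bin <- pmin(floor(image * bins), bins - 1L) + 1L  # 1..bins

  # tile index boundaries (rows and columns split as evenly as possible)
  row_edges <- floor(seq(0L, h, length.out = tiles + 1L))
  col_edges <- floor(seq(0L, w, length.out = tiles + 1L))

  luts <- array(0, c(tiles, tiles, bins))
  centers_r <- numeric(tiles); centers_c <- numeric(tiles)
  for (tr in seq_len(tiles)) {
    rows <- (row_edges[tr] + 1L):row_edges[tr + 1L]
    centers_r[tr] <- mean(range(rows))
    for (tc in seq_len(tiles)) {
      cols <- (col_edges[tc] + 1L):col_edges[tc + 1L]
      if (tr == 1L) centers_c[tc] <- mean(range(cols))
      counts <- tabulate(bin[rows, cols], nbins = bins)
      n_px <- length(rows) * length(cols)
      ceiling_ <- clip * n_px / bins
      excess <- sum(pmax(counts - ceiling_, 0))
      counts <- pmin(counts, ceiling_) + excess / bins
      luts[tr, tc, ] <- cumsum(counts) / n_px
    }
  }

  # bilinear blend of the four surrounding tile-center mappings
  px_r <- matrix(rep(seq_len(h), times = w), h, w)
  px_c <- matrix(rep(seq_len(w), each = h), h, w)
  locate <- function(px, centers) {
    lo <- findInterval(px, centers)          # 0..tiles
    lo <- pmin(pmax(lo, 1L), max(tiles - 1L, 1L))
    hi <- pmin(lo + 1L, tiles)
    denom <- centers[hi] - centers[lo]
    wgt <- ifelse(denom > 0, (px - centers[lo]) / denom, 0)
    wgt <- pmin(pmax(wgt, 0), 1)
    list(lo = lo, hi = hi, w = wgt)
  }
  lr <- locate(as.vector(px_r), centers_r)
  lc <- locate(as.vector(px_c), centers_c)
  b <- as.vector(bin)
  v00 <- luts[cbind(lr$lo, lc$lo, b)]
  v01 <- luts[cbind(lr$lo, lc$hi, b)]
  v10 <- luts[cbind(lr$hi, lc$lo, b)]
  v11 <- luts[cbind(lr$hi, lc$hi, b)]
  out <- (1 - lr$w) * ((1 - lc$w) * v00 + lc$w * v01) +
         lr$w       * ((1 - lc$w) * v10 + lc$w * v11)
  matrix(pmin(pmax(out, 0), 1), h, w)
}

#' Adaptive mean thresholding
#'
#' A pixel maps to 1 iff its intensity exceeds the mean over its centered
#' `block` x `block` neighborhood (replicate borders) plus `offset`; else 0.
#' Applied after edge detection, this keeps only the locally strongest
#' contours and suppresses low-level gradient noise.
#'
#' @param image Numeric matrix.
#' @param block Odd neighborhood size, >= 3 and at most `min(dim(image))`.
#' @param offset Added to the local mean before comparison.
#' @return Binary matrix (values 0/1) of the input's shape.
#' @export
adaptive_threshold <- function(image, block = 11L, offset = 0.02) {
  assert_gray_image(image)
  stop_if_not_scalar_number(block, "block", min = 3, integer = TRUE)
  if (block %% 2L == 0L) stop("`block` must be odd", call. = FALSE)
  if (block > min(dim(image)))
    stop("`block` exceeds the image size", call. = FALSE)
  h <- nrow(image); w <- ncol(image)
  r <- (block - 1L) %/% 2L
  # replicate-pad then box-filter via a 2-D integral image
  p <- image[c(rep(1L, r), seq_len(h), rep(h, r)),
             c(rep(1L, r), seq_len(w), rep(w, r))]
  cs <- apply(apply(p, 2L, cumsum), 1L, cumsum)  # transposed integral image
  cs <- rbind(0, cbind(0, t(cs)))                # (h+2r+1) x (w+2r+1)
  i1 <- seq_len(h); j1 <- seq_len(w)
  sums <- cs[i1 + block, j1 + block, drop = FALSE] -
          cs[i1, j1 + block, drop = FALSE] -
          cs[i1 + block, j1, drop = FALSE] +
          cs[i1, j1, drop = FALSE]
  local_mean <- sums / (block * block)
  out <- (image > local_mean + offset) * 1
  out
}

#' Enhancement options
#'
#' @param method Edge operator mixed into the network input: `"sobel"`,
#'   `"scharr"`, or `"none"`.
#' @param blend_weight Fraction of the normalized edge magnitude mixed into
#'   the original image, in `[0,1]`. 0 returns the (optionally CLAHE'd)
#'   image; 1 returns the pure edge component.
#' @param use_clahe Apply [clahe()] before edge detection.
#' @param clahe_clip,clahe_tiles CLAHE parameters.
#' @param use_adaptive_threshold Binarize the normalized edge magnitude with
#'   [adaptive_threshold()] before blending.
#' @param at_block,at_offset Adaptive-threshold parameters.
#' @return Object of class `enhance_options`.
#' @export
enhance_options <- function(method = c("sobel", "scharr", "none"),
                            blend_weight = 0.5,
                            use_clahe = FALSE, clahe_clip = 2,
                            clahe_tiles = 8L,
                            use_adaptive_threshold = FALSE,
                            at_block = 11L, at_offset = 0.02) {
  method <- match.arg(method)
  stop_if_not_scalar_number(blend_weight, "blend_weight", min = 0, max = 1)
  stop_if_not_scalar_number(clahe_clip, "clahe_clip", min = 0, strict_min = TRUE)
  stop_if_not_scalar_number(clahe_tiles, "clahe_tiles", min = 1, integer = TRUE)
  stop_if_not_scalar_number(at_block, "at_block", min = 3, integer = TRUE)
  if (at_block %% 2L == 0L) stop("`at_block` must be odd", call. = FALSE)
  stop_if_not_scalar_number(at_offset, "at_offset")
  structure(list(method = method, blend_weight = blend_weight,
                 use_clahe = isTRUE(use_clahe),
                 clahe_clip = clahe_clip,
                 clahe_tiles = as.integer(clahe_tiles),
                 use_adaptive_threshold = isTRUE(use_adaptive_threshold),
                 at_block = as.integer(at_block), at_offset = at_offset),
            class = "enhance_options")
}

#' Edge-enhance an image for network input
#'
#' Pipeline: optional CLAHE, then (unless `method = "none"`) edge magnitude
#' by [edge_map()], min-max normalized to `[0,1]`, optionally binarized by
#' [adaptive_threshold()], and finally blended with the source:
#' `out = (1 - blend_weight) * image + blend_weight * edge_component`.
#' With `method = "none"` the (optionally CLAHE'd) image is returned
#' unchanged otherwise. Output intensities stay in `[0,1]`.
#'
#' @param image Numeric matrix with intensities in `[0,1]`.
#' @param options An [enhance_options()].
#' @return Matrix in `[0,1]` with the input's shape.
#' @export
enhance_image <- function(image, options = enhance_options()) {
  assert_gray_image(image)
  if (!inherits(options, "enhance_options"))
    options <- do.call(enhance_options, options)
  img <- image
  if (options$use_clahe)
    img <- clahe(img, options$clahe_clip, options$clahe_tiles)
  if (options$method == "none") return(img)
  mag <- edge_map(img, options$method)$magnitude
  rng <- range(mag)
  edge <- if (rng[2] > rng[1]) (mag - rng[1]) / (rng[2] - rng[1]) else mag * 0
  if (options$use_adaptive_threshold)
    edge <- adaptive_threshold(edge, options$at_block, options$at_offset)
  out <- (1 - options$blend_weight) * img + options$blend_weight * edge
  pmin(pmax(out, 0), 1)
}
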