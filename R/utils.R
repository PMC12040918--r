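# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's `.Random.seed`, so seeded generators do
#' not perturb the global RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' @noRd
stop_if_not_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                      integer = FALSE, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (strict_min) {
    if (x <= min) stop(sprintf("`%s` must be > %s", name, min), call. = FALSE)
  } else if (x < min) {
    stop(sprintf("`%s` must be >= %s", name, min), call. = FALSE)
  }
  if (x > max) stop(sprintf("`%s` must be <= %s", name, max), call. = FALSE)
  if (integer && x != as.integer(x))
    stop(sprintf("`%s` must be an integer", name), call. = FALSE)
  invisible(x)
}

#' @noRd
is_binary_raster <- function(x) {
  is.matrix(x) && is.numeric(x) && all(x == 0 | x == 1)
}

#' @noRd
assert_gray_image <- function(x, name = "image") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("`%s` must be a numeric matrix", name), call. = FALSE)
  invisible(x)
}

#' @noRd
assert_same_shape <- function(a, b, what = "rasters") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("%s must share one shape (%s vs %s)", what,
                 paste(dim(a), collapse = "x"),
                 paste(dim(b), collapse = "x")), call. = FALSE)
  invisible(NULL)
}

# Canonical channel order used everywhere in the package.
CLASS_ORDER <- c("lungs", "heart", "clavicles", "background")
STRUCTURE_CLASSES <- c("lungs", "heart", "clavicles")

#' Derive a 32-bit sub-seed from a base seed and an index
#' @noRd
derive_seed <- function(base_seed, index) {
  (as.double(base_seed) * 2654435761 + as.double(index) * 40503) %% 2147483647
}
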