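# Shared fixtures and independent oracles.

# small deterministic phantom dataset
tiny_dataset <- function(n = 4, size = 64, seed = 101) {
  generate_dataset(n, phantom_spec(size, size, seed = seed))
}

# Independent brute-force evaluation of the gradient double sum:
# out(i,j) = sum_{u,v in -1..1} I(i+u, j+v) * k(u+2, v+2), nested loops,
# out-of-range pixels resolved by an index-mapping rule.
brute_conv3x3 <- function(img, kernel, border) {
  h <- nrow(img); w <- ncol(img)
  px <- function(i, j) {
    if (border == "zero") {
      if (i < 1 || i > h || j < 1 || j > w) return(0)
    } else if (border == "replicate") {
      i <- min(max(i, 1), h); j <- min(max(j, 1), w)
    } else if (border == "reflect") {
      if (i < 1) i <- 2 - i
      if (i > h) i <- 2 * h - i
      if (j < 1) j <- 2 - j
      if (j > w) j <- 2 * w - j
    }
    img[i, j]
  }
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    acc <- 0
    for (u in -1:1) for (v in -1:1)
      acc <- acc + px(i + u, j + v) * kernel[u + 2, v + 2]
    out[i, j] <- acc
  }
  out
}

# independent global histogram equalization (cdf of the binned image)
global_hist_eq <- function(img, bins = 256) {
  b <- pmin(floor(img * bins), bins - 1) + 1
  matrix(stats::ecdf(b)(b), nrow(img), ncol(img))
}

# vertical step image: left half 0, right half `h` (by column)
step_image <- function(n = 16, h = 0.3) {
  matrix(rep(c(rep(0, n / 2), rep(h, n / 2)), each = n), n, n)
}

# cheap order-sensitive checksum for comparing tensors
digest_vec <- function(a) c(sum(a), sum(a * seq_along(a)))

random_binary_pair <- function(size = 12, p = 0.4) {
  list(pred = matrix(rbinom(size * size, 1, p), size, size),
       truth = matrix(rbinom(size * size, 1, p), size, size))
}
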