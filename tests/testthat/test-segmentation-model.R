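make_stack <- function(counts, size = 30) {
  # named list of binary matrices with the requested pixel counts
  out <- list()
  for (nm in names(counts)) {
    m <- matrix(0, size, size)
    if (counts[[nm]] > 0) m[seq_len(counts[[nm]])] <- 1
    out[[nm]] <- m
  }
  out
}

test_that("class weights are inverse to frequency with mean one", {
  # equal pixel counts: both weights 1
  w <- compute_class_weights(list(make_stack(list(a = 50, b = 50))))
  expect_equal(unname(w), c(1, 1))
  # frequencies (0.9, 0.1) -> mean-1 weights (0.2, 1.8)
  w <- compute_class_weights(list(make_stack(list(a = 90, b = 10))))
  expect_equal(unname(w), c(0.2, 1.8))
  expect_equal(mean(w), 1)
  # invariance to uniform scaling of all pixel counts
  w10 <- compute_class_weights(list(make_stack(list(a = 900, b = 100), 40)))
  expect_equal(unname(w10), unname(w))
  # a class with zero pixels is an explicit, named error
  expect_error(compute_class_weights(list(make_stack(list(a = 5, b = 0)))),
               "b")
})

test_that("class weights from phantoms are ordered inverse to frequency", {
  ds <- tiny_dataset(4, size = 64, seed = 70)
  w <- compute_class_weights(ds)
  counts <- colSums(vapply(ds, function(s) vapply(s$masks, sum, numeric(1)),
                           numeric(4)) |> t())
  expect_equal(mean(w), 1)
  expect_identical(order(w), order(1 / counts))
  expect_gt(w[["clavicles"]], w[["lungs"]])
})

test_that("focal loss matches its closed forms", {
  # p_t = 1: zero loss (up to the documented clamp)
  expect_equal(focal_loss(1, 1, alpha = 1, gamma = 2), 0, tolerance = 1e-6)
  expect_equal(focal_loss(0, 0, alpha = 3, gamma = 0.5), 0,
               tolerance = 1e-6)
  # gamma = 0, alpha = 1: plain cross-entropy
  p <- c(0.2, 0.6, 0.9); t <- c(1, 0, 1)
  pt <- ifelse(t == 1, p, 1 - p)
  expect_equal(focal_loss(p, t, alpha = 1, gamma = 0), mean(-log(pt)))
  # worked value: (1 - 0.5)^2 * (-log 0.5) = 0.25 * log 2
  expect_equal(focal_loss(0.5, 1, alpha = 1, gamma = 2), 0.25 * log(2))
  expect_error(focal_loss(0.5, 1, alpha = 0), "alpha")
  expect_error(focal_loss(0.5, 1, gamma = -1), "gamma")
})

test_that("focal loss is monotone in p_t and bounded by cross-entropy", {
  ps <- seq(0.05, 0.95, by = 0.05)
  losses <- vapply(ps, function(p) focal_loss(p, 1, 1, 2), numeric(1))
  expect_true(all(diff(losses) < 0))
  for (g in c(0, 0.5, 2, 5)) {
    fl <- vapply(ps, function(p) focal_loss(p, 1, 1, g), numeric(1))
    ce <- vapply(ps, function(p) focal_loss(p, 1, 1, 0), numeric(1))
    expect_true(all(fl <= ce + 1e-12))
  }
  # per-channel alpha weighting scales each channel's contribution
  pr <- array(0.5, c(2, 2, 2)); tg <- array(1, c(2, 2, 2))
  expect_equal(focal_loss(pr, tg, alpha = c(2, 2), gamma = 0),
               2 * focal_loss(pr, tg, alpha = 1, gamma = 0))
})

test_that("polynomial decay follows the printed formula", {
  cfg <- train_config(epochs = 10, lr_initial = 1e-3, lr_end = 1e-5,
                      decay_steps = 100, power = 1)
  expect_equal(poly_decay_lr(0, cfg), 1e-3)
  expect_equal(poly_decay_lr(100, cfg), 1e-5)
  expect_equal(poly_decay_lr(50, cfg), (1e-3 + 1e-5) / 2)
  # steps beyond decay_steps clamp
  expect_equal(poly_decay_lr(1000, cfg), 1e-5)
  # monotone non-increasing for power >= 1
  for (pw in c(1, 2, 3.5)) {
    cfg$power <- pw
    lrs <- poly_decay_lr(0:120, cfg)
    expect_true(all(diff(lrs) <= 1e-15))
  }
  cfg$decay_steps <- 0L
  expect_error(poly_decay_lr(1, cfg), "decay_steps")
  expect_error(poly_decay_lr(-1, train_config()), "step")
})

test_that("the U-Net forward pass honors shape and range contracts", {
  spec <- unet_spec(depth = 2, base_filters = 4, out_channels = 4)
  model <- build_unet(spec, seed = 1)
  x <- matrix(runif(64 * 64), 64, 64)
  probs <- cxrseg:::unet_forward(model, x)$probs
  expect_identical(dim(probs), c(64L, 64L, 4L))
  expect_true(all(probs > 0 & probs < 1))
  # zeroed final projection: sigma(0) = 0.5 everywhere
  m0 <- model
  m0$params$out$W[] <- 0
  m0$params$out$b[] <- 0
  expect_true(all(cxrseg:::unet_forward(m0, x)$probs == 0.5))
  expect_error(cxrseg:::unet_forward(model, matrix(0, 30, 30)),
               "divisible")
  # same seed, same weights
  expect_identical(build_unet(spec, seed = 1)$params, model$params)
})

test_that("backpropagation matches finite differences", {
  set.seed(2)
  model <- build_unet(unet_spec(depth = 2, base_filters = 3,
                                out_channels = 2), seed = 3)
  x <- array(runif(16 * 16), c(16, 16, 1))
  y <- array(rbinom(16 * 16 * 2, 1, 0.4), c(16, 16, 2))
  alpha <- c(0.7, 1.3); gamma <- 2
  fw <- cxrseg:::unet_forward(model, x, want_cache = TRUE)
  gz <- cxrseg:::focal_loss_grad_z(fw$probs, y, alpha, gamma)
  gr <- cxrseg:::unet_backward(model, fw$cache, gz)
  lossfun <- function(m)
    focal_loss(cxrseg:::unet_forward(m, x)$probs, y, alpha, gamma)
  eps <- 1e-6
  for (nm in c("enc1a", "enc2b", "bota", "dec2a", "dec1b", "out")) {
    idx <- sample(length(model$params[[nm]]$W), 4)
    for (i in idx) {
      m1 <- model; m1$params[[nm]]$W[i] <- m1$params[[nm]]$W[i] + eps
      m2 <- model; m2$params[[nm]]$W[i] <- m2$params[[nm]]$W[i] - eps
      num <- (lossfun(m1) - lossfun(m2)) / (2 * eps)
      expect_equal(gr[[nm]]$gW[i], num, tolerance = 1e-3)
    }
  }
})

test_that("predict_masks thresholds strictly and idempotently", {
  model <- build_unet(unet_spec(depth = 1, base_filters = 2), seed = 5)
  img <- matrix(runif(32 * 32), 32, 32)
  # probabilities exactly at the threshold map to zero
  m0 <- model; m0$params$out$W[] <- 0; m0$params$out$b[] <- 0
  pr <- predict_masks(m0, img, threshold = 0.5)
  expect_true(all(vapply(pr$masks, function(m) all(m == 0), logical(1))))
  # threshold 0: every probability exceeds it
  pr0 <- predict_masks(model, img, threshold = 0)
  expect_true(all(vapply(pr0$masks, function(m) all(m == 1), logical(1))))
  # binarization is idempotent
  pr5 <- predict_masks(model, img, threshold = 0.5)
  again <- lapply(pr5$masks, function(m) (m > 0.5) * 1)
  expect_identical(again, pr5$masks)
  expect_named(pr5$prob_maps, c("lungs", "heart", "clavicles", "background"))
})

test_that("training descends, records history, and follows the schedule", {
  ds <- tiny_dataset(6, size = 32, seed = 80)
  cfg <- train_config(epochs = 8, batch_size = 3, seed = 42,
                      enhance = enhance_options(method = "sobel"))
  fit <- train_model(ds, unet_spec(depth = 2, base_filters = 4), cfg,
                     validation = tiny_dataset(2, size = 32, seed = 81))
  h <- fit$history
  expect_identical(nrow(h), cfg$epochs)
  expect_lt(h$train_loss[cfg$epochs], h$train_loss[1])
  expect_equal(h$lr[1], cfg$lr_initial)
  expect_equal(h$lr, poly_decay_lr(0:(cfg$epochs - 1), cfg))
  expect_equal(poly_decay_lr(cfg$decay_steps, cfg), cfg$lr_end)
  expect_false(anyNA(h$val_loss))
  expect_true(all(h$train_acc >= 0 & h$train_acc <= 1))
  # same seed and data: identical history and weights
  fit2 <- train_model(ds, unet_spec(depth = 2, base_filters = 4), cfg,
                      validation = tiny_dataset(2, size = 32, seed = 81))
  expect_identical(fit2$history, fit$history)
  expect_identical(fit2$model$params, fit$model$params)
  expect_error(train_model(ds[0], unet_spec(), cfg), "empty")
})

test_that("enhancement changes only input tensors, never labels", {
  ds <- tiny_dataset(3, size = 32, seed = 82)
  plain <- cxrseg:::prepare_tensors(ds, enhance_options(method = "none",
                                                        blend_weight = 0))
  sobel <- cxrseg:::prepare_tensors(ds, enhance_options(method = "sobel"))
  expect_identical(lapply(plain$y, function(a) digest_vec(a)),
                   lapply(sobel$y, function(a) digest_vec(a)))
  expect_false(identical(plain$x, sobel$x))
})

test_that("checkpoints round-trip through disk", {
  model <- build_unet(unet_spec(depth = 2, base_filters = 4), seed = 6)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, f)
  back <- load_checkpoint(f)
  expect_identical(back$params, model$params)
  expect_identical(back$spec, model$spec)
  img <- matrix(runif(32 * 32), 32, 32)
  expect_identical(predict_masks(back, img), predict_masks(model, img))
})
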