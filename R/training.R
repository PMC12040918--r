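# Training: inverse-frequency class weights, class-weighted focal loss,
# polynomial learning-rate decay, Adam, and the epoch loop.

#' Training configuration
#'
#' @param epochs Number of training epochs (>= 1).
#' @param batch_size Mini-batch size.
#' @param gamma Focal-loss focusing parameter (>= 0); 0 recovers plain
#'   class-weighted cross-entropy.
#' @param lr_initial,lr_end Initial and final learning rate
#'   (`lr_end <= lr_initial`).
#' @param decay_steps Steps over which the rate decays; defaults to
#'   `epochs` (the schedule is stepped once per epoch).
#' @param power Polynomial degree of the decay (> 0); 1 is linear.
#' @param seed Seed controlling weight initialization and batch shuffling.
#' @param threshold Mask binarization cut in `(0,1)`.
#' @param enhance An [enhance_options()] applied to every image before it
#'   enters the network.
#' @return Object of class `train_config`.
#' @export
train_config <- function(epochs = 50L, batch_size = 4L, gamma = 2,
                         lr_initial = 1e-3, lr_end = 1e-5,
                         decay_steps = NULL, power = 1, seed = 42L,
                         threshold = 0.5, enhance = enhance_options()) {
  stop_if_not_scalar_number(epochs, "epochs", min = 1, integer = TRUE)
  stop_if_not_scalar_number(batch_size, "batch_size", min = 1, integer = TRUE)
  stop_if_not_scalar_number(gamma, "gamma", min = 0)
  stop_if_not_scalar_number(lr_initial, "lr_initial", min = 0,
                            strict_min = TRUE)
  stop_if_not_scalar_number(lr_end, "lr_end", min = 0)
  if (lr_end > lr_initial) stop("lr_end must be <= lr_initial", call. = FALSE)
  if (is.null(decay_steps)) decay_steps <- epochs
  stop_if_not_scalar_number(decay_steps, "decay_steps", min = 1,
                            integer = TRUE)
  stop_if_not_scalar_number(power, "power", min = 0, strict_min = TRUE)
  stop_if_not_scalar_number(seed, "seed", integer = TRUE)
  stop_if_not_scalar_number(threshold, "threshold", min = 0, max = 1)
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0,1)", call. = FALSE)
  if (!inherits(enhance, "enhance_options"))
    enhance <- do.call(enhance_options, enhance)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), gamma = gamma,
                 lr_initial = lr_initial, lr_end = lr_end,
                 decay_steps = as.integer(decay_steps), power = power,
                 seed = as.integer(seed), threshold = threshold,
                 enhance = enhance),
            class = "train_config")
}

#' Inverse-frequency class weights
#'
#' The frequency of class `c` is its pixel count divided by the total pixel
#' count over all classes; the raw weight is `1 / frequency`, rescaled so
#' the weights average 1. Rarer classes therefore receive larger weights,
#' compensating for the heavy class imbalance between lungs, heart, and
#' clavicles.
#'
#' @param dataset A `cxr_dataset` (weights are computed from its masks), or
#'   a list of `mask_stack`s.
#' @return Named numeric vector of positive weights in canonical class
#'   order, mean exactly 1.
#' @export
compute_class_weights <- function(dataset) {
  stacks <- if (inherits(dataset, "cxr_dataset"))
    lapply(dataset, function(s) s$masks) else dataset
  classes <- names(stacks[[1L]])
  counts <- vapply(classes, function(cls)
    sum(vapply(stacks, function(m) sum(m[[cls]]), numeric(1))), numeric(1))
  zero <- classes[counts == 0]
  if (length(zero))
    stop("class with zero pixels across the dataset: ",
         paste(zero, collapse = ", "), call. = FALSE)
  freq <- counts / sum(counts)
  w <- 1 / freq
  w / mean(w)
}

#' Focal loss
#'
#' Elementwise `-alpha * (1 - p_t)^gamma * log(p_t)` with
#' `p_t = prob` where `target = 1` and `1 - prob` otherwise, averaged over
#' all elements. `p_t` is clamped to `[eps, 1 - eps]` before the logarithm.
#' With `gamma = 0`, `alpha = 1` this is plain binary cross-entropy; larger
#' `gamma` down-weights well-classified elements so training concentrates on
#' hard pixels.
#'
#' @param prob Predicted probabilities (any numeric array, values in
#'   `(0,1]`).
#' @param target Binary targets of the same shape.
#' @param alpha Class weight(s): a positive scalar, or for H x W x K arrays
#'   a vector of length K applied per channel.
#' @param gamma Focusing parameter, >= 0.
#' @param eps Clamp applied to `p_t` before the log (default `1e-7`).
#' @return Mean loss (single number).
#' @export
#' @examples
#' focal_loss(0.5, 1, alpha = 1, gamma = 2)  # 0.25 * log(2)
focal_loss <- function(prob, target, alpha = 1, gamma = 2, eps = 1e-7) {
  if (any(alpha <= 0)) stop("alpha must be > 0", call. = FALSE)
  if (gamma < 0) stop("gamma must be >= 0", call. = FALSE)
  if (length(prob) != length(target))
    stop("prob and target must have one shape", call. = FALSE)
  a <- expand_alpha(alpha, prob)
  pt <- ifelse(target == 1, prob, 1 - prob)
  pt <- pmin(pmax(pt, eps), 1 - eps)
  mean(-a * (1 - pt)^gamma * log(pt))
}

# recycle a per-class alpha vector over the channels of an H x W x K array
expand_alpha <- function(alpha, prob) {
  if (length(alpha) == 1L) return(alpha)
  d <- dim(prob)
  if (is.null(d) || length(d) != 3L || d[3] != length(alpha))
    stop("vector alpha requires an H x W x K array with K = length(alpha)",
         call. = FALSE)
  array(rep(alpha, each = d[1] * d[2]), d)
}

# gradient of the mean focal loss w.r.t. the pre-sigmoid logits
focal_loss_grad_z <- function(prob, target, alpha, gamma, eps = 1e-7) {
  a <- expand_alpha(alpha, prob)
  sgn <- ifelse(target == 1, 1, -1)
  pt <- ifelse(target == 1, prob, 1 - prob)
  inside <- (pt > eps) & (pt < 1 - eps)
  ptc <- pmin(pmax(pt, eps), 1 - eps)
  term1 <- if (gamma > 0) gamma * (1 - ptc)^(gamma - 1) * log(ptc) else 0
  dl_dpt <- a * (term1 - (1 - ptc)^gamma / ptc) * inside
  dl_dpt * sgn * prob * (1 - prob) / length(prob)
}

#' Polynomial learning-rate decay
#'
#' Evaluates
#' `(lr_initial - lr_end) * (1 - step / decay_steps)^power + lr_end`,
#' with steps beyond `decay_steps` clamped to `decay_steps` (the schedule
#' holds at `lr_end`).
#'
#' @param step Current step (0-based); may be a vector.
#' @param config A [train_config()] (or any list with `lr_initial`,
#'   `lr_end`, `decay_steps`, `power`).
#' @return Learning rate(s).
#' @export
poly_decay_lr <- function(step, config) {
  if (any(step < 0)) stop("step must be >= 0", call. = FALSE)
  if (config$decay_steps == 0) stop("decay_steps must be > 0", call. = FALSE)
  s <- pmin(step, config$decay_steps)
  (config$lr_initial - config$lr_end) *
    (1 - s / config$decay_steps)^config$power + config$lr_end
}

# ---- tensors and Adam -----------------------------------------------------

# enhanced input tensors (H x W x 1) and label tensors (H x W x K);
# enhancement touches only the inputs, never the labels
prepare_tensors <- function(dataset, enhance, class_names = CLASS_ORDER) {
  xs <- lapply(dataset, function(s)
    array(enhance_image(s$image, enhance), c(dim(s$image), 1L)))
  ys <- lapply(dataset, function(s) {
    d <- dim(s$image)
    array(unlist(s$masks[class_names], use.names = FALSE),
          c(d[1], d[2], length(class_names)))
  })
  list(x = xs, y = ys)
}

adam_init <- function(params) {
  lapply(params, function(p)
    list(mW = p$W * 0, vW = p$W * 0,
         mb = p$b * 0, vb = p$b * 0))
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (nm in names(params)) {
    g <- grads[[nm]]; s <- state[[nm]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$gW
    s$vW <- beta2 * s$vW + (1 - beta2) * g$gW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$gb
    s$vb <- beta2 * s$vb + (1 - beta2) * g$gb^2
    params[[nm]]$W <- params[[nm]]$W - lr * (s$mW / bc1) /
      (sqrt(s$vW / bc2) + eps)
    params[[nm]]$b <- params[[nm]]$b - lr * (s$mb / bc1) /
      (sqrt(s$vb / bc2) + eps)
    state[[nm]] <- s
  }
  list(params = params, state = state)
}

#' Train a U-Net on a dataset
#'
#' Applies the configured enhancement to every image once, computes
#' inverse-frequency class weights from the training masks, and optimizes
#' the class-weighted focal loss with Adam at the polynomially decayed
#' learning rate (one schedule step per epoch, 0-based). All randomness
#' (weight init, batch shuffling) flows from `config$seed`, so a fixed seed
#' reproduces the history on one machine.
#'
#' @param dataset Nonempty `cxr_dataset`, all samples at one size divisible
#'   by `2^unet$depth`.
#' @param unet A [unet_spec()].
#' @param config A [train_config()].
#' @param validation Optional `cxr_dataset` scored after every epoch; if
#'   absent the validation columns are `NA`.
#' @param verbose Print a line per epoch.
#' @return List with `model` (trained `unet_model`) and `history` (one row
#'   per epoch: `epoch`, `train_loss`, `val_loss`, `train_acc`, `val_acc`,
#'   `lr`).
#' @export
train_model <- function(dataset, unet, config = train_config(),
                        validation = NULL, verbose = FALSE) {
  if (length(dataset) == 0) stop("dataset is empty", call. = FALSE)
  if (!inherits(unet, "unet_spec")) unet <- do.call(unet_spec, unet)
  weights <- compute_class_weights(dataset)
  tens <- prepare_tensors(dataset, config$enhance)
  vtens <- if (!is.null(validation))
    prepare_tensors(validation, config$enhance)
  n <- length(tens$x)

  with_seed(config$seed, {
    model <- build_unet(unet)
    state <- adam_init(model$params)
    t_step <- 0L
    hist <- data.frame(epoch = seq_len(config$epochs), train_loss = NA_real_,
                       val_loss = NA_real_, train_acc = NA_real_,
                       val_acc = NA_real_, lr = NA_real_)
    for (epoch in seq_len(config$epochs)) {
      lr <- poly_decay_lr(epoch - 1L, config)
      perm <- sample.int(n)
      batches <- split(perm, ceiling(seq_along(perm) / config$batch_size))
      ep_loss <- 0; ep_acc <- 0
      for (bi in batches) {
        grads <- NULL
        b_loss <- 0; b_acc <- 0
        for (j in bi) {
          fw <- unet_forward(model, tens$x[[j]], want_cache = TRUE)
          p <- fw$probs; y <- tens$y[[j]]
          b_loss <- b_loss + focal_loss(p, y, alpha = weights,
                                        gamma = config$gamma)
          b_acc <- b_acc + mean(((p > config$threshold) * 1) == y)
          gz <- focal_loss_grad_z(p, y, weights, config$gamma)
          g <- unet_backward(model, fw$cache, gz)
          grads <- if (is.null(grads)) g else
            mapply(function(acc, gg) list(gW = acc$gW + gg$gW,
                                          gb = acc$gb + gg$gb),
                   grads, g, SIMPLIFY = FALSE)
        }
        nb <- length(bi)
        grads <- lapply(grads, function(g) list(gW = g$gW / nb,
                                                gb = g$gb / nb))
        t_step <- t_step + 1L
        upd <- adam_step(model$params, grads, state, lr, t_step)
        model$params <- upd$params
        state <- upd$state
        ep_loss <- ep_loss + b_loss
        ep_acc <- ep_acc + b_acc
      }
      hist$train_loss[epoch] <- ep_loss / n
      hist$train_acc[epoch] <- ep_acc / n
      hist$lr[epoch] <- lr
      if (!is.null(vtens)) {
        vl <- 0; va <- 0
        for (j in seq_along(vtens$x)) {
          p <- unet_forward(model, vtens$x[[j]])$probs
          vl <- vl + focal_loss(p, vtens$y[[j]], alpha = weights,
                                gamma = config$gamma)
          va <- va + mean(((p > config$threshold) * 1) == vtens$y[[j]])
        }
        hist$val_loss[epoch] <- vl / length(vtens$x)
        hist$val_acc[epoch] <- va / length(vtens$x)
      }
      if (verbose)
        message(sprintf("epoch %3d  loss %.5f  acc %.4f  lr %.2e", epoch,
                        hist$train_loss[epoch], hist$train_acc[epoch], lr))
    }
    list(model = model, history = hist)
  })
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS archive holding the architecture spec
#' serialized as JSON plus the weight arrays and class names.
#'
#' @param model A `unet_model`.
#' @param path Checkpoint path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(spec_json = jsonlite::toJSON(unclass(model$spec),
                                            auto_unbox = TRUE),
               params = model$params,
               class_names = model$class_names), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  spec <- do.call(unet_spec, jsonlite::fromJSON(x$spec_json))
  structure(list(spec = spec, params = x$params,
                 class_names = x$class_names),
            class = "unet_model")
}

#' Write a training history to CSV
#' @param history The `history` data frame from [train_model()].
#' @param path Output CSV path.
#' @export
write_history <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}
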