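# Evaluation: Dice, Jaccard, pixel accuracy, the combined Dice+Jaccard
# objective, per-class reporting, stratified k-fold cross-validation, and
# the paired t test for method comparison.

assert_binary_pair <- function(pred, truth) {
  if (!is_binary_raster(pred) || !is_binary_raster(truth))
    stop("pred and truth must be binary matrices", call. = FALSE)
  assert_same_shape(pred, truth, "pred and truth")
}

#' Dice coefficient
#'
#' `2 |S intersect G| / (|S| + |G|)` for binary rasters. When both masks are
#' empty the score is 1: a correct "nothing present" prediction is not
#' penalized.
#'
#' @param pred,truth Binary matrices of one shape.
#' @return Value in `[0,1]`.
#' @export
dice <- function(pred, truth) {
  assert_binary_pair(pred, truth)
  s <- sum(pred); g <- sum(truth)
  if (s + g == 0) return(1)
  2 * sum(pred * truth) / (s + g)
}

#' Jaccard index
#'
#' `|S intersect G| / |S union G|`; both-empty masks score 1. Related to the
#' Dice coefficient by `J = D / (2 - D)`.
#'
#' @inheritParams dice
#' @return Value in `[0,1]`.
#' @export
jaccard <- function(pred, truth) {
  assert_binary_pair(pred, truth)
  inter <- sum(pred * truth)
  uni <- sum(pred) + sum(truth) - inter
  if (uni == 0) return(1)
  inter / uni
}

#' Pixel accuracy
#'
#' Fraction of pixels where `pred == truth`.
#'
#' @param pred,truth Matrices of one shape.
#' @return Value in `[0,1]`.
#' @export
pixel_accuracy <- function(pred, truth) {
  assert_same_shape(pred, truth, "pred and truth")
  mean(pred == truth)
}

# per-image mean Dice / Jaccard over the structure classes (background
# excluded so the dominant trivial class cannot inflate the objective)
image_dice_jaccard <- function(pred_stack, truth_stack,
                               classes = setdiff(names(truth_stack),
                                                 "background")) {
  d <- mean(vapply(classes, function(cl)
    dice(pred_stack[[cl]], truth_stack[[cl]]), numeric(1)))
  j <- mean(vapply(classes, function(cl)
    jaccard(pred_stack[[cl]], truth_stack[[cl]]), numeric(1)))
  c(dice = d, jaccard = j)
}

#' Combined segmentation objective
#'
#' Mean Dice plus mean Jaccard over a set of images,
#' `(1/n) sum_i D_i + (1/n) sum_i J_i`, where each image's D and J are the
#' mean over the structure classes (lungs, heart, clavicles; background
#' excluded). The value lies in `[0, 2]` and equals 2 only for pixel-perfect
#' predictions.
#'
#' @param predictions,truths Equal-length lists of mask stacks (named lists
#'   of binary matrices).
#' @return Single value in `[0, 2]`.
#' @export
combined_objective <- function(predictions, truths) {
  if (length(predictions) != length(truths))
    stop("predictions and truths must have equal length", call. = FALSE)
  if (length(predictions) == 0) stop("empty mask lists", call. = FALSE)
  dj <- vapply(seq_along(predictions), function(i)
    image_dice_jaccard(predictions[[i]], truths[[i]]), numeric(2))
  mean(dj["dice", ]) + mean(dj["jaccard", ])
}

#' Evaluate a model on a test dataset
#'
#' Enhances each test image per `config$enhance`, predicts masks at
#' `config$threshold`, and reports per-class accuracy, Dice, and Jaccard
#' averaged over the test samples, together with the combined
#' Dice+Jaccard objective. Accuracy is also summarized over all channels
#' (`overall_accuracy`) and over the structure channels only
#' (`structure_accuracy`), since the background class dominates the pixel
#' count.
#'
#' @param model A trained `unet_model`.
#' @param test Nonempty `cxr_dataset`.
#' @param config The [train_config()] used in training (enhancement and
#'   threshold are taken from it).
#' @return Object of class `metrics_report`: a data frame with one row per
#'   class (canonical order) and columns `class`, `accuracy`, `dice`,
#'   `jaccard`; attributes `combined_objective`, `n_samples`,
#'   `overall_accuracy`, `structure_accuracy`, and `per_sample` (the
#'   unaggregated per-sample metric arrays).
#' @export
evaluate_model <- function(model, test, config = train_config()) {
  if (length(test) == 0) stop("empty test set", call. = FALSE)
  classes <- model$class_names
  n <- length(test)
  acc <- matrix(NA_real_, n, length(classes),
                dimnames = list(NULL, classes))
  dic <- acc; jac <- acc
  preds <- vector("list", n); truths <- vector("list", n)
  overall <- numeric(n)
  for (i in seq_len(n)) {
    s <- test[[i]]
    pr <- predict_masks(model, s$image, threshold = config$threshold,
                        options = config$enhance)
    preds[[i]] <- pr$masks
    truths[[i]] <- s$masks
    for (cl in classes) {
      acc[i, cl] <- pixel_accuracy(pr$masks[[cl]], s$masks[[cl]])
      dic[i, cl] <- dice(pr$masks[[cl]], s$masks[[cl]])
      jac[i, cl] <- jaccard(pr$masks[[cl]], s$masks[[cl]])
    }
    overall[i] <- mean(vapply(classes, function(cl)
      pixel_accuracy(pr$masks[[cl]], s$masks[[cl]]), numeric(1)))
  }
  report <- data.frame(class = classes,
                       accuracy = colMeans(acc),
                       dice = colMeans(dic),
                       jaccard = colMeans(jac),
                       row.names = NULL)
  structure(report,
            class = c("metrics_report", "data.frame"),
            combined_objective = combined_objective(preds, truths),
            n_samples = n,
            overall_accuracy = mean(overall),
            structure_accuracy =
              mean(acc[, intersect(STRUCTURE_CLASSES, classes)]),
            per_sample = list(accuracy = acc, dice = dic, jaccard = jac))
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n = %d, combined objective %.4f\n",
              attr(x, "n_samples"), attr(x, "combined_objective")))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Export a metrics report
#'
#' CSV mirrors the per-class table layout (class, method, accuracy, dice,
#' jaccard); JSON additionally carries the combined objective and sample
#' count.
#'
#' @param report A `metrics_report`.
#' @param path Output path ending in `.csv` or `.json`.
#' @param method Label written into the `method` column.
#' @export
write_report <- function(report, path, method = "unet") {
  df <- cbind(class = report$class, method = method,
              report[c("accuracy", "dice", "jaccard")])
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(method = method, classes = df,
           combined_objective = attr(report, "combined_objective"),
           overall_accuracy = attr(report, "overall_accuracy"),
           n_samples = attr(report, "n_samples")),
      path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Plan k folds, optionally stratified
#'
#' Identifiers are shuffled under `seed` and dealt round-robin onto folds
#' through a single rotating cursor, one stratum at a time, so fold sizes
#' differ by at most one globally and each stratum is spread across folds as
#' evenly as integer arithmetic allows.
#'
#' @param dataset A `cxr_dataset`.
#' @param k Number of folds, `2 <= k <= length(dataset)`.
#' @param strata Optional per-sample stratum labels (dataset order).
#' @param seed Integer seed.
#' @return Object of class `fold_plan`: list with `k`, `assignments` (named
#'   integer vector id -> fold), `strata`, `seed`.
#' @export
make_folds <- function(dataset, k = 10L, strata = NULL, seed = 1L) {
  ids <- dataset_ids(dataset)
  stop_if_not_scalar_number(k, "k", min = 2, integer = TRUE)
  if (k > length(ids)) stop("k exceeds the dataset size", call. = FALSE)
  if (!is.null(strata) && length(strata) != length(ids))
    stop("strata length must match the dataset size", call. = FALSE)
  lab <- if (is.null(strata)) rep("all", length(ids)) else as.character(strata)
  with_seed(seed, {
    assignments <- integer(length(ids))
    names(assignments) <- ids
    cursor <- 0L
    fold_order <- sample.int(k)   # rotation start is itself randomized
    for (sl in unique(lab)) {
      members <- sample(ids[lab == sl])
      for (m in members) {
        assignments[m] <- fold_order[(cursor %% k) + 1L]
        cursor <- cursor + 1L
      }
    }
    structure(list(k = as.integer(k), assignments = assignments,
                   strata = strata, seed = as.integer(seed)),
              class = "fold_plan")
  })
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> k = %d, sizes: %s\n", x$k,
              paste(tabulate(x$assignments, x$k), collapse = ", ")))
  invisible(x)
}

#' k-fold cross-validation of the segmentation pipeline
#'
#' Trains one model per fold on the remaining folds and evaluates it on the
#' held-out fold; returns the per-fold reports plus across-fold means.
#'
#' @param dataset A `cxr_dataset` covered by `folds`.
#' @param unet A [unet_spec()].
#' @param config A [train_config()]; fold `i` trains with seed
#'   `config$seed + i` so folds are independent but reproducible.
#' @param folds A [make_folds()] plan over `dataset`.
#' @param verbose Print per-fold progress.
#' @return Object of class `cv_result`: list with `reports` (per fold),
#'   `aggregate` (data frame of across-fold mean accuracy/dice/jaccard per
#'   class), and `mean_objective`.
#' @export
cross_validate <- function(dataset, unet, config, folds, verbose = FALSE) {
  ids <- dataset_ids(dataset)
  if (!all(ids %in% names(folds$assignments)))
    stop("fold plan does not cover the dataset", call. = FALSE)
  reports <- vector("list", folds$k)
  for (f in seq_len(folds$k)) {
    test_ids <- names(folds$assignments)[folds$assignments == f]
    train_ids <- setdiff(ids, test_ids)
    cfg <- config
    cfg$seed <- config$seed + f
    fit <- tryCatch(
      train_model(dataset[train_ids], unet, cfg),
      error = function(e)
        stop(sprintf("fold %d: %s", f, conditionMessage(e)), call. = FALSE))
    reports[[f]] <- evaluate_model(fit$model, dataset[test_ids], cfg)
    if (verbose)
      message(sprintf("fold %d/%d: objective %.4f", f, folds$k,
                      attr(reports[[f]], "combined_objective")))
  }
  classes <- reports[[1]]$class
  agg <- data.frame(
    class = classes,
    accuracy = rowMeans(vapply(reports, function(r) r$accuracy,
                               numeric(length(classes)))),
    dice = rowMeans(vapply(reports, function(r) r$dice,
                           numeric(length(classes)))),
    jaccard = rowMeans(vapply(reports, function(r) r$jaccard,
                              numeric(length(classes)))),
    row.names = NULL)
  structure(list(reports = reports, aggregate = agg,
                 mean_objective = mean(vapply(reports, attr, numeric(1),
                                              "combined_objective"))),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d folds, mean objective %.4f\n",
              length(x$reports), x$mean_objective))
  print.data.frame(x$aggregate, digits = 4)
  invisible(x)
}

#' Paired t test between per-sample scores of two methods
#'
#' Computes `t = mean(d) / (sd(d) / sqrt(n))` on the paired differences
#' `d = a - b` (sample standard deviation, `n - 1` denominator) and a
#' two-sided p value from the exact t distribution with `n - 1` degrees of
#' freedom.
#'
#' @param scores_a,scores_b Equal-length numeric vectors of per-sample
#'   scores (n >= 2).
#' @return List with `t`, `p`, `df`, and `mean_diff`.
#' @export
paired_t_test <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b))
    stop("score vectors must have equal length", call. = FALSE)
  n <- length(scores_a)
  if (n < 2) stop("need at least two pairs", call. = FALSE)
  d <- scores_a - scores_b
  s <- stats::sd(d)
  if (s == 0)
    stop("degenerate case: all paired differences are identical",
         call. = FALSE)
  t <- mean(d) / (s / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1), df = n - 1L,
       mean_diff = mean(d))
}
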