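#' Deterministic (optionally stratified) sample splits
#'
#' Partitions sample ids into the requested fractions with largest-remainder
#' rounding, after a seeded shuffle. With `stratify = TRUE`, the allocation
#' is applied within each class of `labels`, so class proportions are
#' preserved to within one sample per stratum.
#'
#' @param ids Character vector of sample ids.
#' @param fractions Positive fractions summing to 1 (within 1e-9). Unnamed
#'   fractions of length 2 are named train/test; length 3 train/test/
#'   validation.
#' @param labels Class label per id (required when `stratify = TRUE`).
#' @param stratify Preserve class proportions per partition.
#' @param seed Integer seed; the split is a pure function of its inputs.
#' @return An object of class `split_spec`: named list of id vectors.
#' @export
split_samples <- function(ids, fractions = c(train = 0.7, test = 0.3),
                          labels = NULL, stratify = FALSE, seed = 1) {
  if (abs(sum(fractions) - 1) > 1e-9)
    .stop_input("fractions must sum to 1")
  if (any(fractions <= 0)) .stop_input("fractions must be positive")
  if (is.null(names(fractions)))
    names(fractions) <- if (length(fractions) == 2) c("train", "test")
    else if (length(fractions) == 3) c("train", "test", "validation")
    else paste0("part", seq_along(fractions))
  if (anyDuplicated(ids)) .stop_input("duplicate sample ids")

  alloc <- function(n) {
    target <- fractions * n
    sizes <- floor(target)
    short <- n - sum(sizes)
    if (short > 0) {
      extra <- order(target - sizes, decreasing = TRUE)[seq_len(short)]
      sizes[extra] <- sizes[extra] + 1
    }
    sizes
  }
  set.seed(seed)
  parts <- stats::setNames(vector("list", length(fractions)), names(fractions))
  if (stratify) {
    if (is.null(labels)) .stop_input("stratified splits need labels")
    if (length(labels) != length(ids)) .stop_input("labels must match ids")
    for (cls in unique(as.character(labels))) {
      cls_ids <- sample(ids[as.character(labels) == cls])
      sizes <- alloc(length(cls_ids))
      stops <- cumsum(sizes)
      starts <- c(1, utils::head(stops, -1) + 1)
      for (j in seq_along(fractions))
        if (sizes[j] > 0)
          parts[[j]] <- c(parts[[j]], cls_ids[starts[j]:stops[j]])
      if (any(sizes == 0))
        .stop_input("class '%s' absent from partition '%s' under stratification",
                    cls, names(fractions)[which(sizes == 0)[1L]])
    }
  } else {
    shuffled <- sample(ids)
    sizes <- alloc(length(ids))
    stops <- cumsum(sizes)
    starts <- c(1, utils::head(stops, -1) + 1)
    for (j in seq_along(fractions))
      parts[[j]] <- if (sizes[j] > 0) shuffled[starts[j]:stops[j]] else character(0)
  }
  structure(parts, class = "split_spec", fractions = fractions,
            seed = seed, stratified = stratify)
}

#' Train a probabilistic binary subtype classifier
#'
#' A random forest (500 trees by default) over a small feature panel,
#' predicting the probability of the named positive class (e.g. T-high or
#' T-low membership). Training is deterministic given the seed.
#'
#' @param features Samples x features numeric matrix or data.frame.
#' @param labels Binary label per sample (logical, 0/1, or two-level factor).
#' @param positive Value of `labels` treated as the positive class; defaults
#'   to the second factor level (or `TRUE`/`1`).
#' @param ntree Number of trees (default 500).
#' @param seed Integer seed.
#' @return An object of class `subtype_classifier` with a [predict()] method
#'   returning positive-class probabilities.
#' @export
train_subtype_classifier <- function(features, labels, positive = NULL,
                                     ntree = 500, seed = 1) {
  features <- as.data.frame(features)
  if (any(!vapply(features, is.numeric, logical(1))) ||
      any(!is.finite(as.matrix(features))))
    .stop_input("features must be finite and numeric")
  y <- factor(labels)
  if (nlevels(y) != 2)
    .stop_input("labels must contain exactly two classes")
  if (any(table(y) < 2)) .stop_input("each class needs at least 2 samples")
  if (is.null(positive)) positive <- levels(y)[2L]
  positive <- as.character(positive)
  if (!positive %in% levels(y)) .stop_input("positive class not found in labels")
  set.seed(seed)
  rf <- randomForest::randomForest(x = features, y = y, ntree = ntree)
  structure(list(rf = rf, features = colnames(features),
                 positive = positive, ntree = ntree, seed = seed),
            class = "subtype_classifier")
}

#' @param object A `subtype_classifier`.
#' @param newdata Samples x features matrix or data.frame containing the
#'   training feature columns.
#' @param ... Unused.
#' @return Numeric vector of positive-class probabilities.
#' @rdname train_subtype_classifier
#' @export
predict.subtype_classifier <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  missing <- setdiff(object$features, colnames(newdata))
  if (length(missing)) .stop_input("missing feature: '%s'", missing[1L])
  pr <- stats::predict(object$rf, newdata[, object$features, drop = FALSE],
                       type = "prob")
  as.vector(pr[, object$positive])
}

#' ROC curve and AUC by threshold sweep
#'
#' The AUC equals the Mann-Whitney probability that a random positive
#' outscores a random negative, with ties counted one half. ROC points are
#' generated by sweeping the distinct score values as thresholds; the curve
#' starts at (0, 0) and ends at (1, 1) with both coordinates nondecreasing.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (the positive class is `TRUE`, `1`, or the
#'   second factor level); both classes must be present.
#' @return An object of class `classifier_eval`: `auc`, `roc` (data.frame
#'   `fpr`, `tpr`), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  y <- if (is.logical(labels)) labels
  else if (is.numeric(labels)) labels == max(labels)
  else factor(labels) == levels(factor(labels))[2L]
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) .stop_input("both classes must be present")
  if (any(!is.finite(scores))) .stop_input("scores must be finite")
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  block_last <- rev(!duplicated(rev(ss)))   # last index of each tied block
  tpr <- cumsum(ys)[block_last] / n1
  fpr <- cumsum(!ys)[block_last] / n0
  roc <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  structure(list(auc = auc, roc = roc, n_pos = n1, n_neg = n0),
            class = "classifier_eval")
}

#' @export
print.classifier_eval <- function(x, ...) {
  cat(sprintf("AUC = %.4f (%d positives, %d negatives)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}
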