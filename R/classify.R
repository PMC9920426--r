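## From-scratch k-nearest-neighbour classification with Euclidean distance
## (the deployed on-watch detector), confusion counting and the standard
## accuracy/sensitivity/specificity metrics, plus adapter seams that delegate
## SVM and decision trees to established libraries for the offline grid study.

#' Euclidean distance between two feature vectors
#'
#' @param a,b numeric vectors of equal length.
#' @return `sqrt(sum((a - b)^2))`.
#' @export
euclidean_distance <- function(a, b) {
  if (length(a) != length(b)) {
    stop("euclidean_distance: dimension mismatch (", length(a), " vs ", length(b), ")",
      call. = FALSE
    )
  }
  sqrt(sum((a - b)^2))
}

#' k-nearest-neighbour prediction
#'
#' Predicts the majority label among the `k` training points nearest to `x`
#' in Euclidean distance.  Deterministic tie rules: a distance tie at the
#' k-th neighbour is broken by training-point insertion order (earlier points
#' win), and a vote tie predicts Fall -- in this domain a missed fall is
#' costlier than a false alarm.
#'
#' @param train_x numeric matrix of training feature vectors (rows).
#' @param train_y character vector of labels (`"Fall"` / `"ADL"`).
#' @param x numeric query vector (or matrix of queries, one per row).
#' @param k number of neighbours, `1 <= k <= nrow(train_x)`.
#' @return predicted label(s).
#' @export
knn_predict <- function(train_x, train_y, x, k = 3) {
  train_x <- as.matrix(train_x)
  n <- nrow(train_x)
  if (n == 0) stop("knn_predict: empty training set", call. = FALSE)
  if (length(train_y) != n) stop("knn_predict: label/feature length mismatch", call. = FALSE)
  if (k < 1 || k > n) stop("knn_predict: k must satisfy 1 <= k <= ", n, call. = FALSE)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != ncol(train_x)) {
    stop("knn_predict: query dimension ", ncol(x), " != training dimension ", ncol(train_x),
      call. = FALSE
    )
  }
  # squared distances suffice for ranking
  tx2 <- rowSums(train_x^2)
  vapply(seq_len(nrow(x)), function(i) {
    d2 <- tx2 - 2 * as.numeric(train_x %*% x[i, ]) + sum(x[i, ]^2)
    ord <- order(d2, seq_len(n))[seq_len(k)] # stable: insertion order breaks ties
    votes <- sum(train_y[ord] == LABEL_FALL)
    if (votes >= k - votes) LABEL_FALL else LABEL_ADL
  }, character(1))
}

#' Confusion counts (Fall is the positive class)
#'
#' @param truth,predicted equal-length label vectors.
#' @return a `confusion_counts` list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop("confusion: length mismatch", call. = FALSE)
  }
  structure(
    list(
      TP = sum(truth == LABEL_FALL & predicted == LABEL_FALL),
      TN = sum(truth == LABEL_ADL & predicted == LABEL_ADL),
      FP = sum(truth == LABEL_ADL & predicted == LABEL_FALL),
      FN = sum(truth == LABEL_FALL & predicted == LABEL_ADL)
    ),
    class = "confusion_counts"
  )
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' Accuracy = (TP+TN)/(TP+TN+FP+FN); sensitivity = TP/(TP+FN) (proportion of
#' actual falls predicted correctly); specificity = TN/(TN+FP).  A metric
#' whose denominator is zero is undefined and returned as `NA`.
#'
#' @param counts a `confusion_counts`.
#' @return list with `accuracy`, `sensitivity`, `specificity` (`NA` where
#'   undefined).
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- counts$TP + counts$TN + counts$FP + counts$FN
  pos <- counts$TP + counts$FN
  neg <- counts$TN + counts$FP
  list(
    accuracy = if (total > 0) (counts$TP + counts$TN) / total else NA_real_,
    sensitivity = if (pos > 0) counts$TP / pos else NA_real_,
    specificity = if (neg > 0) counts$TN / neg else NA_real_
  )
}

## ---------------------------------------------------------------------------
## Classifier adapters: a uniform fit/predict seam over the algorithms of the
## grid study.  kNN is this package's own implementation; SVM and decision
## trees delegate to e1071 and rpart.

#' Describe a classifier configuration
#'
#' @param algorithm `"knn"`, `"svm"` or `"dt"`.
#' @param k neighbours (kNN).
#' @param kernel `"radial"` or `"polynomial"` (SVM).
#' @param split `"gini"`, `"entropy"` or `"log_loss"` (decision tree;
#'   entropy and log loss are the same information criterion, kept as
#'   distinct grid entries).
#' @return a `classifier_spec`.
#' @export
classifier_spec <- function(algorithm = c("knn", "svm", "dt"), k = 3,
                            kernel = c("radial", "polynomial"),
                            split = c("gini", "entropy", "log_loss")) {
  algorithm <- match.arg(algorithm)
  spec <- switch(algorithm,
    knn = list(algorithm = "knn", k = as.integer(k)),
    svm = list(algorithm = "svm", kernel = match.arg(kernel)),
    dt = list(algorithm = "dt", split = match.arg(split))
  )
  spec$id <- switch(algorithm,
    knn = paste0(k, "NN"),
    svm = paste0(sub("radial", "rbf", sub("polynomial", "poly", spec$kernel)), "_SVM"),
    dt = paste0(spec$split, "_DT")
  )
  structure(spec, class = "classifier_spec")
}

#' The 15 algorithm variants of the configuration grid
#'
#' kNN with k = 1..10, SVM with radial-basis and polynomial kernels, and
#' decision trees with Gini, entropy and log-loss splitting.
#'
#' @return list of `classifier_spec`.
#' @export
default_algorithms <- function() {
  c(
    lapply(1:10, function(k) classifier_spec("knn", k = k)),
    list(
      classifier_spec("svm", kernel = "radial"),
      classifier_spec("svm", kernel = "polynomial"),
      classifier_spec("dt", split = "gini"),
      classifier_spec("dt", split = "entropy"),
      classifier_spec("dt", split = "log_loss")
    )
  )
}

## Train/predict under a classifier_spec. "Training" a kNN is dataset storage.
fit_classifier <- function(spec, train_x, train_y) {
  stopifnot(inherits(spec, "classifier_spec"))
  train_x <- as.matrix(train_x)
  if (spec$algorithm == "knn") {
    list(spec = spec, x = train_x, y = train_y)
  } else if (spec$algorithm == "svm") {
    df <- as.data.frame(train_x)
    df$.label <- factor(train_y, levels = c(LABEL_ADL, LABEL_FALL))
    list(spec = spec, model = e1071::svm(.label ~ ., data = df, kernel = spec$kernel))
  } else {
    df <- as.data.frame(train_x)
    df$.label <- factor(train_y, levels = c(LABEL_ADL, LABEL_FALL))
    parms <- list(split = if (spec$split == "gini") "gini" else "information")
    list(spec = spec, model = rpart::rpart(.label ~ .,
      data = df, method = "class",
      parms = parms
    ))
  }
}

predict_classifier <- function(fit, x) {
  x <- as.matrix(x)
  if (fit$spec$algorithm == "knn") {
    ke <- min(fit$spec$k, nrow(fit$x))
    knn_predict(fit$x, fit$y, x, k = ke)
  } else {
    as.character(stats::predict(fit$model, newdata = as.data.frame(x), type = "class"))
  }
}
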