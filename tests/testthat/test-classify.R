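# Brute-force kNN oracle: full distance vector, explicit stable sort, majority
# vote with the same safety-first tie rule.
knn_oracle <- function(train_x, train_y, x, k) {
  d <- apply(train_x, 1, function(r) sqrt(sum((r - x)^2)))
  ord <- order(d, seq_along(d))[seq_len(k)]
  votes <- sum(train_y[ord] == "Fall")
  if (votes >= k - votes) "Fall" else "ADL"
}

test_that("euclidean distance matches hand cases and a summation oracle", {
  expect_identical(euclidean_distance(c(0, 0), c(3, 4)), 5)
  expect_identical(euclidean_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_error(euclidean_distance(c(1, 2), c(1, 2, 3)), "dimension mismatch")
  set.seed(4)
  for (i in 1:100) {
    a <- rnorm(12)
    b <- rnorm(12)
    acc <- 0
    for (j in 1:12) acc <- acc + (a[j] - b[j])^2
    expect_equal(euclidean_distance(a, b), sqrt(acc), tolerance = 1e-12)
  }
})

test_that("kNN prediction follows distances and majority votes", {
  train <- matrix(c(0, 1, 10), ncol = 1)
  labels <- c("ADL", "ADL", "Fall")
  expect_identical(knn_predict(train, labels, 2, k = 3), "ADL") # 2 of 3 neighbours
  expect_identical(knn_predict(train, labels, 10, k = 1), "Fall") # exact training point
  # k = n: global majority regardless of the query
  expect_identical(knn_predict(train, labels, -100, k = 3), "ADL")
  expect_error(knn_predict(train, labels, 2, k = 0), "k must")
  expect_error(knn_predict(train, labels, 2, k = 4), "k must")
  expect_error(knn_predict(matrix(numeric(0), ncol = 1), character(0), 2, k = 1), "empty training")
})

test_that("vote ties predict Fall (safety-first)", {
  train <- matrix(c(0, 2), ncol = 1)
  expect_identical(knn_predict(train, c("ADL", "Fall"), 1, k = 2), "Fall")
})

test_that("kNN matches the brute-force oracle on random instances", {
  set.seed(10)
  for (i in 1:120) {
    n <- sample(5:200, 1)
    d <- sample(1:12, 1)
    k <- sample(1:min(9, n), 1)
    train <- matrix(rnorm(n * d), ncol = d)
    labels <- sample(c("Fall", "ADL"), n, replace = TRUE)
    x <- rnorm(d)
    expect_identical(
      knn_predict(train, labels, x, k = k),
      knn_oracle(train, labels, x, k)
    )
  }
})

test_that("prediction is invariant to training-set permutation", {
  set.seed(12)
  train <- matrix(rnorm(60 * 4), ncol = 4)
  labels <- sample(c("Fall", "ADL"), 60, replace = TRUE)
  xs <- matrix(rnorm(10 * 4), ncol = 4)
  base <- knn_predict(train, labels, xs, k = 3)
  for (r in 1:5) {
    p <- sample(60)
    expect_identical(knn_predict(train[p, ], labels[p], xs, k = 3), base)
  }
})

test_that("confusion counts enumerate the four cells", {
  cm <- confusion(c("Fall", "Fall", "ADL", "ADL"), c("Fall", "ADL", "Fall", "ADL"))
  expect_identical(unlist(cm[c("TP", "FN", "FP", "TN")]), c(TP = 1L, FN = 1L, FP = 1L, TN = 1L))
  all_right <- confusion(c("Fall", "ADL"), c("Fall", "ADL"))
  expect_identical(all_right$FP + all_right$FN, 0L)
  empty <- confusion(character(0), character(0))
  expect_identical(unlist(empty[c("TP", "TN", "FP", "FN")]), c(TP = 0L, TN = 0L, FP = 0L, FN = 0L))
  expect_error(confusion("Fall", c("Fall", "ADL")), "length mismatch")
})

test_that("metrics follow their defining ratios, undefined where denominators vanish", {
  perfect <- classification_metrics(confusion(c("Fall", "ADL"), c("Fall", "ADL")))
  expect_equal(unlist(perfect), c(accuracy = 1, sensitivity = 1, specificity = 1))
  m <- classification_metrics(structure(list(TP = 90, FN = 10, TN = 85, FP = 5),
    class = "confusion_counts"
  ))
  expect_equal(m$sensitivity, 0.90)
  expect_equal(m$specificity, 85 / 90, tolerance = 1e-9)
  expect_equal(m$accuracy, 175 / 190, tolerance = 1e-9)
  no_pos <- classification_metrics(confusion(c("ADL", "ADL"), c("ADL", "Fall")))
  expect_true(is.na(no_pos$sensitivity))
  expect_false(is.na(no_pos$specificity))
})

test_that("accuracy decomposes into the class-weighted mean of sensitivity and specificity", {
  set.seed(13)
  for (i in 1:50) {
    truth <- sample(c("Fall", "ADL"), 40, replace = TRUE)
    pred <- sample(c("Fall", "ADL"), 40, replace = TRUE)
    cm <- confusion(truth, pred)
    m <- classification_metrics(cm)
    P <- cm$TP + cm$FN
    N <- cm$TN + cm$FP
    if (P > 0 && N > 0) {
      expect_equal(m$accuracy, (m$sensitivity * P + m$specificity * N) / (P + N),
        tolerance = 1e-12
      )
    }
  }
})

test_that("SVM and decision-tree adapters train and predict through the same seam", {
  tab <- tiny_table()
  x <- as.matrix(tab[setdiff(names(tab), META_COLUMNS)])
  y <- tab$label
  for (spec in list(
    classifier_spec("svm", kernel = "radial"),
    classifier_spec("svm", kernel = "polynomial"),
    classifier_spec("dt", split = "gini"),
    classifier_spec("dt", split = "entropy"),
    classifier_spec("dt", split = "log_loss")
  )) {
    fit <- fit_classifier(spec, x, y)
    pred <- predict_classifier(fit, x)
    expect_true(all(pred %in% c("Fall", "ADL")))
    # separable synthetic data: training accuracy should be high
    expect_gt(mean(pred == y), 0.9)
  }
  expect_identical(length(default_algorithms()), 15L)
})
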