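# Enumerate all non-empty subsets explicitly (oracle for the closed form).
subset_count_oracle <- function(n) {
  count <- 0L
  for (mask in 1:(2^n - 1)) count <- count + 1L
  count
}

test_that("feature-subset counting: closed form, binomial sum and enumeration agree", {
  expect_identical(count_feature_subsets(12), 4095L)
  expect_identical(count_feature_subsets(1), 1L)
  expect_identical(count_feature_subsets(5), subset_count_oracle(5))
  expect_identical(count_feature_subsets(4), 15L)
  expect_error(count_feature_subsets(0), ">= 1")
})

test_that("the default grid has 1,535,625 configurations", {
  expect_equal(grid_size(grid_space()), 1535625)
  # singleton space with a one-element pool
  s1 <- grid_space(
    frequencies = 50, window_sizes = 9,
    algorithms = list(classifier_spec("knn", k = 3)),
    sensors = "accelerometer"
  )
  s1$feature_pool <- "accel_max"
  expect_equal(grid_size(s1), 1)
  # 2x2x2 space with pool 2: 8 x 3 = 24
  s2 <- grid_space(
    frequencies = c(50, 25), window_sizes = c(5, 9),
    algorithms = list(classifier_spec("knn", k = 1), classifier_spec("knn", k = 3)),
    sensors = "accelerometer"
  )
  s2$feature_pool <- c("accel_max", "accel_min")
  expect_equal(grid_size(s2), 24)
  # the accelerometer-only restriction: 5 x 5 x 15 x 15 = 5625
  expect_equal(grid_size(grid_space(sensors = "accelerometer")), 5625)
})

test_that("k-fold splits are disjoint, exhaustive, stratified and seeded", {
  labels <- rep(c("Fall", "ADL"), c(60, 40))
  folds <- kfold_split(labels, k = 5, seed = 3)
  expect_identical(sort(unique(folds)), 1:5)
  expect_true(all(table(folds) == 20))
  for (f in 1:5) {
    expect_identical(sum(labels[folds == f] == "Fall"), 12L)
    expect_identical(sum(labels[folds == f] == "ADL"), 8L)
  }
  expect_identical(kfold_split(labels, k = 5, seed = 3), folds) # determinism
  expect_false(identical(kfold_split(labels, k = 5, seed = 4), folds))
  expect_error(kfold_split(rep(c("Fall", "ADL"), c(3, 50)), k = 5), "fewer points")
  expect_error(kfold_split(labels, k = 1), "k must be >= 2")
})

test_that("cross-validation is perfect on separable features and chance on shuffled labels", {
  set.seed(20)
  x <- rbind(
    matrix(rnorm(100 * 3, mean = 10), ncol = 3),
    matrix(rnorm(100 * 3, mean = -10), ncol = 3)
  )
  colnames(x) <- c("accel_max_x", "accel_max_y", "accel_max_z")
  tab <- as.data.frame(x)
  tab$label <- rep(c("Fall", "ADL"), each = 100)
  tab$user_id <- "U1"
  tab$cohort <- "YP"
  tab$activity <- "F01"
  tab$trial <- 1L
  tab$start <- 0
  res <- cross_validate(tab, classifier_spec("knn", k = 3), seed = 1)
  expect_equal(res$accuracy_mean, 1)
  expect_equal(res$accuracy_sd, 0)

  # label shuffle: accuracy near chance, averaged over seeds
  accs <- vapply(1:5, function(s) {
    set.seed(100 + s)
    tab$label <- sample(tab$label) # balanced random labels
    cross_validate(tab, classifier_spec("knn", k = 3), seed = s)$accuracy_mean
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.1)
})

test_that("pooled confusion equals the sum of fold confusions", {
  tab <- tiny_table()
  res <- cross_validate(tab, classifier_spec("knn", k = 3), seed = 2)
  expect_identical(res$confusion$TP, sum(res$folds$TP))
  expect_identical(res$confusion$TN, sum(res$folds$TN))
  expect_identical(res$confusion$FP, sum(res$folds$FP))
  expect_identical(res$confusion$FN, sum(res$folds$FN))
  expect_identical(
    res$confusion$TP + res$confusion$TN + res$confusion$FP + res$confusion$FN,
    nrow(tab)
  )
})

test_that("the grid enumerator visits exactly grid_size distinct points", {
  space <- grid_space(
    frequencies = 50, window_sizes = 9,
    algorithms = list(classifier_spec("knn", k = 1), classifier_spec("knn", k = 3)),
    sensors = "accelerometer"
  )
  expect_equal(grid_size(space), 30)
  res <- run_grid(tiny_dataset(), space, seed = 1)
  expect_identical(nrow(res), 30L)
  expect_identical(anyDuplicated(res[c("frequency", "window_s", "algorithm", "features")]), 0L)
  expect_true(all(res$accuracy_mean >= 0 & res$accuracy_mean <= 1))
  # the full-FS-1 subset rows use 4 pool elements = 12 feature columns
  expect_true(any(res$n_features == 4))
  # budgeted subsample visits that many points, seeded
  sub <- run_grid(tiny_dataset(), space, budget = 7, seed = 5)
  expect_identical(nrow(sub), 7L)
  expect_identical(run_grid(tiny_dataset(), space, budget = 7, seed = 5), sub)
  expect_error(run_grid(tiny_dataset(), space, budget = 0), "budget")
})

test_that("grid results sort to a best configuration", {
  space <- grid_space(
    frequencies = 50, window_sizes = 9,
    algorithms = list(classifier_spec("knn", k = 3)),
    sensors = "accelerometer"
  )
  res <- best_configuration(run_grid(tiny_dataset(), space, seed = 1))
  expect_true(all(diff(res$accuracy_mean) <= 0))
  expect_gte(res$accuracy_mean[1], max(res$accuracy_mean))
})

test_that("personalised evaluation restricts to one user and validates input", {
  tab <- tiny_table()
  res <- personalised_eval(tab, "U1", classifier_spec("knn", k = 3), seed = 1)
  expect_gte(res$accuracy_mean, 0.9) # separable single-user synthetic data
  expect_error(personalised_eval(tab, "nobody"), "unknown user_id")
})

test_that("personalised models are comparable against the all-users model per user", {
  recs <- cached("yp6_dataset", generate_dataset(yp_protocol(6), seed = 303))
  tab <- cached("yp6_table", feature_table(recs))
  all_res <- cross_validate(tab, classifier_spec("knn", k = 3), seed = 7)
  users <- unique(tab$user_id)
  rows <- lapply(users, function(u) {
    pr <- personalised_eval(tab, u, classifier_spec("knn", k = 3), seed = 7)
    data.frame(user = u, accuracy = pr$accuracy_mean, sd = pr$accuracy_sd)
  })
  cmp <- do.call(rbind, rows)
  expect_identical(nrow(cmp), length(users))
  expect_true(all(cmp$accuracy >= 0 & cmp$accuracy <= 1))
  expect_true(all(cmp$sd >= 0))
  expect_true(all(is.finite(c(all_res$accuracy_mean, all_res$accuracy_sd))))
  # single-user synthetic data is near-separable, so personalised accuracy
  # stays high (the stability contrast the field reports needs real data)
  expect_true(all(cmp$accuracy >= 0.9))
})
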