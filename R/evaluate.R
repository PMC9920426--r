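## 5-fold cross-validation, the exhaustive (frequency, window size, algorithm,
## feature subset) configuration grid, and the ablation modes
## (personalisation, median filtering, vertical acceleration, cohort mixing).

#' Number of non-empty feature subsets of a pool
#'
#' All non-empty subsets of an n-element (sensor, statistic) pool:
#' `2^n - 1`, computed by binomial summation `sum(choose(n, 1:n))` and
#' cross-checked against the closed form.  For the full 12-element pool this
#' is 4095.
#'
#' @param n pool size (>= 1).
#' @return integer subset count.
#' @export
count_feature_subsets <- function(n) {
  if (n < 1) stop("count_feature_subsets: pool size must be >= 1", call. = FALSE)
  total <- sum(choose(n, seq_len(n)))
  stopifnot(isTRUE(all.equal(total, 2^n - 1)))
  as.integer(total)
}

#' Grid search space
#'
#' @param frequencies sampling rates evaluated (Hz).
#' @param window_sizes window sizes evaluated (s).
#' @param algorithms list of [classifier_spec()] (default: the 15 variants of
#'   [default_algorithms()]).
#' @param sensors sensors contributing features (the pool is 4 statistics per
#'   sensor).
#' @param jump_s window stride (s).
#' @return a `grid_space`.
#' @export
grid_space <- function(frequencies = c(50, 40, 25, 10, 5),
                       window_sizes = 5:9,
                       algorithms = default_algorithms(),
                       sensors = SENSORS,
                       jump_s = 1) {
  if (length(frequencies) == 0 || length(window_sizes) == 0 || length(algorithms) == 0) {
    stop("grid_space: empty dimension", call. = FALSE)
  }
  sensors <- match.arg(sensors, SENSORS, several.ok = TRUE)
  structure(
    list(
      frequencies = frequencies, window_sizes = window_sizes,
      algorithms = algorithms, sensors = sensors,
      feature_pool = feature_pool(sensors), jump_s = jump_s
    ),
    class = "grid_space"
  )
}

#' Total number of grid configurations
#'
#' `|frequencies| x |window sizes| x |algorithms| x (2^pool - 1)`; the default
#' space yields 5 x 5 x 15 x 4095 = 1,535,625.
#'
#' @param space a [grid_space()].
#' @return numeric total (may exceed integer range for extended spaces).
#' @export
grid_size <- function(space) {
  stopifnot(inherits(space, "grid_space"))
  length(space$frequencies) * length(space$window_sizes) *
    length(space$algorithms) * count_feature_subsets(length(space$feature_pool))
}

## Decode grid point `index` (1-based) into its configuration.  Mixed-radix
## order: feature subset fastest, then algorithm, then window, then frequency.
grid_point <- function(space, index) {
  n_sub <- count_feature_subsets(length(space$feature_pool))
  n_alg <- length(space$algorithms)
  n_win <- length(space$window_sizes)
  i <- index - 1
  sub_i <- i %% n_sub
  i <- i %/% n_sub
  alg_i <- i %% n_alg
  i <- i %/% n_alg
  win_i <- i %% n_win
  freq_i <- i %/% n_win
  mask <- sub_i + 1 # subsets are bitmasks 1 .. 2^n - 1
  pool <- space$feature_pool
  subset <- pool[bitwAnd(mask, bitwShiftL(1, seq_along(pool) - 1)) != 0]
  list(
    frequency = space$frequencies[freq_i + 1],
    window_s = space$window_sizes[win_i + 1],
    algorithm = space$algorithms[[alg_i + 1]],
    subset = subset
  )
}

#' Stratified k-fold split
#'
#' Disjoint, exhaustive folds; when stratified, each class is spread across
#' folds so fold class ratios match the dataset's within one point.
#'
#' @param labels label vector.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @param stratified stratify by class (default `TRUE`).
#' @return integer vector of fold assignments (1..k) per point.
#' @export
kfold_split <- function(labels, k = 5, seed = 1, stratified = TRUE) {
  n <- length(labels)
  if (k < 2) stop("kfold_split: k must be >= 2", call. = FALSE)
  with_seed(seed, {
    folds <- integer(n)
    if (stratified) {
      for (cl in unique(labels)) {
        idx <- which(labels == cl)
        if (length(idx) < k) {
          stop("kfold_split: class '", cl, "' has fewer points (", length(idx),
            ") than folds (", k, ")",
            call. = FALSE
          )
        }
        folds[sample(idx)] <- rep_len(seq_len(k), length(idx))
      }
    } else {
      if (n < k) stop("kfold_split: fewer points than folds", call. = FALSE)
      folds[sample.int(n)] <- rep_len(seq_len(k), n)
    }
    folds
  })
}

#' Cross-validate one configuration on a feature table
#'
#' Per-fold train/test with the configured classifier; fold-wise accuracy,
#' specificity and sensitivity aggregated to mean and standard deviation.  A
#' degenerate fold (a metric's denominator zero) contributes `NA` to that
#' metric and is skipped in the aggregation.
#'
#' @param table feature table from [feature_table()].
#' @param algorithm a [classifier_spec()].
#' @param columns feature columns to use (default: all feature columns).
#' @param k_folds folds (default 5).
#' @param seed fold-assignment seed.
#' @param stratified stratified folds (default `TRUE`).
#' @return an `eval_result` list: `algorithm`, `columns`, per-fold data.frame
#'   `folds`, pooled `confusion`, and `accuracy_mean/sd`,
#'   `specificity_mean/sd`, `sensitivity_mean/sd`.
#' @export
cross_validate <- function(table, algorithm = classifier_spec("knn", k = 3),
                           columns = NULL, k_folds = 5, seed = 1,
                           stratified = TRUE) {
  x <- feature_matrix(table, columns)
  y <- table$label
  folds <- kfold_split(y, k = k_folds, seed = seed, stratified = stratified)
  per_fold <- vector("list", k_folds)
  pooled <- list(TP = 0L, TN = 0L, FP = 0L, FN = 0L)
  for (f in seq_len(k_folds)) {
    test <- folds == f
    fit <- fit_classifier(algorithm, x[!test, , drop = FALSE], y[!test])
    pred <- predict_classifier(fit, x[test, , drop = FALSE])
    cm <- confusion(y[test], pred)
    for (nm in names(pooled)) pooled[[nm]] <- pooled[[nm]] + cm[[nm]]
    m <- classification_metrics(cm)
    per_fold[[f]] <- data.frame(
      fold = f, accuracy = m$accuracy,
      sensitivity = m$sensitivity, specificity = m$specificity,
      TP = cm$TP, TN = cm$TN, FP = cm$FP, FN = cm$FN
    )
  }
  folds_df <- do.call(rbind, per_fold)
  agg <- function(v) c(mean = mean(v, na.rm = TRUE), sd = stats::sd(v[!is.na(v)]))
  acc <- agg(folds_df$accuracy)
  sens <- agg(folds_df$sensitivity)
  spec <- agg(folds_df$specificity)
  structure(
    list(
      algorithm = algorithm, columns = colnames(x), folds = folds_df,
      confusion = structure(pooled, class = "confusion_counts"),
      accuracy_mean = acc[["mean"]], accuracy_sd = acc[["sd"]],
      sensitivity_mean = sens[["mean"]], sensitivity_sd = sens[["sd"]],
      specificity_mean = spec[["mean"]], specificity_sd = spec[["sd"]]
    ),
    class = "eval_result"
  )
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf(
    "<eval_result> %s on %d features: accuracy %.5f (sd %.5f), specificity %.5f, sensitivity %.5f\n",
    x$algorithm$id, length(x$columns), x$accuracy_mean, x$accuracy_sd,
    x$specificity_mean, x$sensitivity_mean
  ))
  invisible(x)
}

#' Run the configuration grid
#'
#' Evaluates grid configurations by 5-fold cross-validation, re-using a
#' cached feature table per (frequency, window size) pair.  Without a budget
#' every one of [grid_size()] points is visited; with a budget, a seeded
#' random subsample of that many points is evaluated (the full default grid
#' has 1,535,625 points, far beyond desk scale at real data sizes).
#'
#' @param recordings list of `fall_recording` at the source rate.
#' @param space a [grid_space()].
#' @param budget optional number of grid points to subsample.
#' @param seed seed for the subsample and the fold assignments.
#' @param k_folds folds per evaluation.
#' @return data.frame with one row per visited grid point: `frequency`,
#'   `window_s`, `algorithm`, `n_features`, `features`, metric means/sds.
#' @export
run_grid <- function(recordings, space = grid_space(), budget = NULL, seed = 1,
                     k_folds = 5) {
  stopifnot(inherits(space, "grid_space"))
  total <- grid_size(space)
  if (!is.null(budget)) {
    if (budget <= 0) stop("run_grid: budget must be positive", call. = FALSE)
    idx <- with_seed(seed, sort(sample(total, min(budget, total))))
  } else {
    idx <- seq_len(total)
  }
  cache <- new.env(parent = emptyenv())
  src_rate <- trace_rate(recordings[[1]]$traces[[1]])
  get_table <- function(freq, win) {
    key <- paste0("f", freq, "w", win)
    if (!exists(key, envir = cache, inherits = FALSE)) {
      assign(key, feature_table(recordings,
        spec = window_spec(win, space$jump_s),
        sensors = space$sensors,
        target_hz = if (freq < src_rate) freq else NULL
      ), envir = cache)
    }
    get(key, envir = cache, inherits = FALSE)
  }
  rows <- lapply(idx, function(i) {
    gp <- grid_point(space, i)
    tab <- get_table(gp$frequency, gp$window_s)
    res <- cross_validate(tab, gp$algorithm,
      columns = feature_columns(gp$subset),
      k_folds = k_folds, seed = seed
    )
    data.frame(
      index = i, frequency = gp$frequency, window_s = gp$window_s,
      algorithm = gp$algorithm$id, n_features = length(gp$subset),
      features = paste(gp$subset, collapse = "+"),
      accuracy_mean = res$accuracy_mean, accuracy_sd = res$accuracy_sd,
      specificity_mean = res$specificity_mean, specificity_sd = res$specificity_sd,
      sensitivity_mean = res$sensitivity_mean, sensitivity_sd = res$sensitivity_sd,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select the best configuration from grid results
#'
#' Orders by accuracy mean (descending), breaking ties by specificity then
#' sensitivity means.
#'
#' @param results data.frame from [run_grid()].
#' @return the results sorted, best configuration first.
#' @export
best_configuration <- function(results) {
  results[order(-results$accuracy_mean, -results$specificity_mean, -results$sensitivity_mean), ]
}

#' Personalised (single-user) evaluation
#'
#' Cross-validates the configuration on one user's windows only, for
#' comparison against the all-users model: a fall detector trained on its
#' wearer's own data against one trained on everyone's.
#'
#' @param table feature table with a `user_id` column.
#' @param user_id user to restrict to.
#' @param algorithm a [classifier_spec()].
#' @param columns feature columns (default all).
#' @param k_folds folds.
#' @param seed fold seed.
#' @return an `eval_result`.
#' @export
personalised_eval <- function(table, user_id, algorithm = classifier_spec("knn", k = 3),
                              columns = NULL, k_folds = 5, seed = 1) {
  sub <- table[table$user_id == user_id, , drop = FALSE]
  if (nrow(sub) == 0) stop("personalised_eval: unknown user_id '", user_id, "'", call. = FALSE)
  counts <- table(sub$label)
  if (length(counts) < 2 || any(counts < k_folds)) {
    stop("personalised_eval: user '", user_id, "' lacks ", k_folds,
      " points in each class",
      call. = FALSE
    )
  }
  cross_validate(sub, algorithm, columns = columns, k_folds = k_folds, seed = seed)
}
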