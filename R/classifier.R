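#' Configuration for the progression-classification experiment
#'
#' @param test_fraction Held-out fraction (default 0.2, i.e. an 0.8/0.2
#'   train/test split).
#' @param n_features Number of patches to keep in whole-brain mode
#'   (default 79, matching the size of the extremity patch set so the two
#'   feature modes are comparable).
#' @param kernel SVM kernel, `"rbf"` (default) or `"linear"`.
#' @param c_grid,gamma_grid Hyperparameter grids (positive).
#' @param cv_folds Cross-validation folds for tuning (default 5).
#' @param stratified Stratify the train/test split by class (default TRUE).
#' @param seed Base seed; each experiment cell derives its own offset from
#'   it.
#' @return Object of class `classifier_config`.
#' @export
classifier_config <- function(test_fraction = 0.2, n_features = 79,
                              kernel = c("rbf", "linear"),
                              c_grid = c(0.01, 0.1, 1, 10, 100),
                              gamma_grid = 10^seq(-4, 1),
                              cv_folds = 5, stratified = TRUE, seed = 1L) {
  kernel <- match.arg(kernel)
  assert_scalar_number(test_fraction, "test_fraction", 1e-9, 1 - 1e-9)
  assert_scalar_number(n_features, "n_features", lo = 1)
  assert_scalar_number(cv_folds, "cv_folds", lo = 2)
  if (length(c_grid) < 1 || any(c_grid <= 0) ||
      length(gamma_grid) < 1 || any(gamma_grid <= 0))
    tp_stop("hyperparameter grids must be nonempty and positive",
            class = "thinpatch_config_error")
  structure(list(test_fraction = test_fraction,
                 n_features = as.integer(n_features), kernel = kernel,
                 c_grid = sort(c_grid), gamma_grid = sort(gamma_grid),
                 cv_folds = as.integer(cv_folds),
                 stratified = isTRUE(stratified), seed = as.integer(seed)),
            class = "classifier_config")
}

#' Deterministic train/test split
#'
#' Test size is `round(test_fraction * n)`. When stratified, each class
#' contributes its rounded share (largest-remainder adjusted), keeping class
#' proportions within one subject of the overall split.
#'
#' @param ids Subject identifiers.
#' @param labels Class labels, same length.
#' @param test_fraction Held-out fraction.
#' @param stratified Preserve class proportions.
#' @param seed Integer seed (same seed, same split).
#' @return List with `train_ids`, `test_ids`.
#' @export
split_train_test <- function(ids, labels, test_fraction = 0.2,
                             stratified = TRUE, seed = 1L) {
  n <- length(ids)
  if (n < 10) tp_stop("need at least 10 subjects to split",
                      class = "thinpatch_validation_error")
  labels <- factor(labels)
  if (nlevels(labels) != 2)
    tp_stop("need exactly two classes", class = "thinpatch_validation_error")
  k <- round(test_fraction * n)
  test_idx <- withr::with_seed(seed, {
    if (stratified) {
      n_c <- table(labels)
      k_c <- round(test_fraction * as.numeric(n_c))
      # largest-remainder adjustment so the total equals round(0.2 * n)
      while (sum(k_c) > k) k_c[which.max(k_c)] <- k_c[which.max(k_c)] - 1L
      while (sum(k_c) < k) k_c[which.min(k_c)] <- k_c[which.min(k_c)] + 1L
      unlist(lapply(seq_along(n_c), function(ci) {
        pool <- which(as.integer(labels) == ci)
        sample(pool, k_c[ci])
      }), use.names = FALSE)
    } else {
      sample(n, k)
    }
  })
  train <- setdiff(seq_len(n), test_idx)
  if (nlevels(droplevels(labels[train])) < 2)
    tp_stop("a class is absent from the training split; re-seed or use ",
            "stratified splitting", class = "thinpatch_split_error")
  list(train_ids = ids[sort(train)], test_ids = ids[sort(test_idx)])
}

#' Filter feature selection by absolute two-sample t-statistic
#'
#' Ranks patches by the absolute pooled-variance two-sample t-statistic
#' between the classes (training data only) and keeps the top `k`. Patches
#' with zero pooled variance have an undefined t and rank last; exact ties
#' break toward the lower patch index.
#'
#' @param x Training feature matrix (subjects x patches).
#' @param y Training class labels (two levels).
#' @param k Number of features to keep.
#' @param name Name for the resulting patch set.
#' @return A [patch_set()] of the selected column indices.
#' @export
select_features <- function(x, y, k = 79, name = "selected") {
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(y) != 2) tp_stop("need exactly two classes",
                               class = "thinpatch_validation_error")
  if (k > ncol(x)) tp_stop("k exceeds the number of available features",
                           class = "thinpatch_config_error")
  g1 <- as.integer(y) == 1L
  n1 <- sum(g1); n2 <- sum(!g1)
  m1 <- colMeans(x[g1, , drop = FALSE])
  m2 <- colMeans(x[!g1, , drop = FALSE])
  v1 <- matrixStats::colVars(x[g1, , drop = FALSE])
  v2 <- matrixStats::colVars(x[!g1, , drop = FALSE])
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  tstat <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  score <- abs(tstat)
  score[!is.finite(score)] <- -Inf  # zero-variance features rank last
  ord <- order(-score, seq_along(score))
  patch_set(ord[seq_len(k)], name = name,
            provenance = sprintf("top %d |t| filter on %d training subjects",
                                 k, nrow(x)))
}

#' @noRd
.stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (ci in seq_len(nlevels(y))) {
    pool <- which(as.integer(y) == ci)
    fold[pool] <- sample(rep(seq_len(k), length.out = length(pool)))
  }
  fold
}

#' Grid-search SVM tuning with stratified k-fold cross-validation
#'
#' Evaluates every (C, gamma) pair by mean fold accuracy on the training
#' set; ties resolve to the smallest C, then the smallest gamma. The final
#' model is refit on the full training set with the winning pair. Folds are
#' stratified; a fold whose training part would lose a class is skipped with
#' a message (only possible when a class has a single member).
#'
#' @param x Training feature matrix.
#' @param y Training labels (two levels).
#' @param config A [classifier_config()].
#' @param seed Seed for the fold assignment.
#' @return List: `model` ([svm_fit()] on all training data),
#'   `best_hyperparameters` (named numeric), `cv_accuracy`, `grid`
#'   (data.frame of all pairs and their CV accuracy).
#' @export
tune_svm <- function(x, y, config = classifier_config(), seed = 1L) {
  x <- as.matrix(x)
  y <- factor(y)
  fold <- withr::with_seed(seed, .stratified_folds(y, config$cv_folds))
  grid <- expand.grid(gamma = config$gamma_grid, C = config$c_grid,
                      KEEP.OUT.ATTRS = FALSE)[, c("C", "gamma")]
  if (config$kernel == "linear") grid <- unique(transform(grid, gamma = 0))
  acc <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    fold_acc <- c()
    for (f in seq_len(config$cv_folds)) {
      tr <- fold != f
      if (nlevels(droplevels(y[tr])) < 2) {
        message("fold ", f, " skipped: single-class training part")
        next
      }
      g <- if (config$kernel == "linear") 1 / ncol(x) else grid$gamma[gi]
      m <- svm_fit(x[tr, , drop = FALSE], y[tr], cost = grid$C[gi],
                   kernel = config$kernel, gamma = g)
      pred <- predict(m, x[!tr, , drop = FALSE])
      fold_acc <- c(fold_acc, mean(pred == y[!tr]))
    }
    acc[gi] <- mean(fold_acc)
  }
  best <- which.max(acc)  # grid ordered by C then gamma: first max wins ties
  g <- if (config$kernel == "linear") 1 / ncol(x) else grid$gamma[best]
  model <- svm_fit(x, y, cost = grid$C[best], kernel = config$kernel,
                   gamma = g)
  list(model = model,
       best_hyperparameters = c(C = grid$C[best], gamma = g),
       cv_accuracy = acc[best],
       grid = cbind(grid, cv_accuracy = acc))
}

#' Evaluate a fitted classifier on held-out subjects
#'
#' Accuracy is the fraction of correctly classified cases of all considered
#' cases.
#'
#' @param model A fitted [svm_fit()] model.
#' @param x_test,y_test Held-out features and labels.
#' @param ids Optional test subject ids for the predictions table.
#' @return List: `test_accuracy`, `predictions` (data.frame with
#'   `subject_id`, `observed`, `predicted`, `correct`).
#' @export
evaluate_classifier <- function(model, x_test, y_test, ids = NULL) {
  if (length(y_test) == 0) tp_stop("empty test set",
                                   class = "thinpatch_validation_error")
  pred <- predict(model, as.matrix(x_test))
  obs <- factor(y_test, levels = model$levels)
  data_ids <- ids %||% rownames(as.matrix(x_test)) %||%
    as.character(seq_along(y_test))
  list(test_accuracy = mean(pred == obs),
       predictions = data.frame(subject_id = data_ids,
                                observed = as.character(obs),
                                predicted = as.character(pred),
                                correct = pred == obs,
                                stringsAsFactors = FALSE))
}

#' @noRd
.one_cell <- function(z, labels_df, feature_mode, roi, config, cell_seed) {
  ids <- labels_df$subject_id
  y <- factor(ifelse(labels_df$progressor, "progressor", "non_progressor"),
              levels = c("non_progressor", "progressor"))
  split <- split_train_test(ids, y, test_fraction = config$test_fraction,
                            stratified = config$stratified, seed = cell_seed)
  tr <- match(split$train_ids, ids)
  te <- match(split$test_ids, ids)
  if (feature_mode == "restricted_roi") {
    sel <- roi  # pre-selected domain set: no further feature selection
  } else {
    sel <- select_features(z[split$train_ids, , drop = FALSE], y[tr],
                           k = config$n_features, name = "wholebrain_selected")
  }
  x_tr <- z[split$train_ids, sel$indices, drop = FALSE]
  x_te <- z[split$test_ids, sel$indices, drop = FALSE]
  tuned <- tune_svm(x_tr, y[tr], config, seed = cell_seed)
  ev <- evaluate_classifier(tuned$model, x_te, y[te], ids = split$test_ids)
  list(outcome = labels_df$measure[1], horizon = labels_df$horizon[1],
       feature_mode = feature_mode, train_ids = split$train_ids,
       test_ids = split$test_ids, selected_patches = sel,
       best_hyperparameters = tuned$best_hyperparameters,
       cv_accuracy = tuned$cv_accuracy, test_accuracy = ev$test_accuracy,
       predictions = ev$predictions, seed = cell_seed)
}

#' Run the full progression-classification experiment
#'
#' One SVM per combination of feature mode (domain-restricted 79-patch set
#' vs. whole-brain with filter selection down to the same size), clinical
#' measure (extremity, total motor, cognitive) and follow-up horizon (Y1,
#' Y3): 12 cells in total. Features are the per-patch normative z-scores;
#' labels come from [label_progressors()]. Within a (measure, horizon) cell
#' both feature modes share the same train/test split so their accuracies
#' are directly comparable.
#'
#' @param map_result A [map_cohort()] result for the patients (z-scores).
#' @param clinical Long clinical data.frame.
#' @param roi The domain-specific [patch_set()].
#' @param config A [classifier_config()].
#' @param measures,horizons Subsets of the default cells, if desired.
#' @return Object of class `progression_experiment`: list of per-cell
#'   reports plus a `summary` data.frame.
#' @export
run_progression_experiment <- function(map_result, clinical, roi,
                                       config = classifier_config(),
                                       measures = c("extremity", "total_motor",
                                                    "cognitive"),
                                       horizons = c("Y1", "Y3")) {
  stopifnot(inherits(map_result, "map_result"), inherits(roi, "patch_set"))
  z <- map_result$z
  reports <- list()
  cell <- 0L
  for (ms in measures) for (h in horizons) {
    labels_df <- label_progressors(clinical, ms, h)
    labels_df <- labels_df[labels_df$subject_id %in% rownames(z), , drop = FALSE]
    cell <- cell + 1L
    cell_seed <- config$seed + cell  # shared by both feature modes
    for (mode in c("restricted_roi", "wholebrain_selected")) {
      reports[[paste(ms, h, mode, sep = ".")]] <-
        .one_cell(z, labels_df, mode, roi, config, cell_seed)
    }
  }
  summary <- do.call(rbind, lapply(reports, function(r)
    data.frame(outcome = r$outcome, horizon = r$horizon,
               feature_mode = r$feature_mode,
               n_train = length(r$train_ids), n_test = length(r$test_ids),
               C = unname(r$best_hyperparameters["C"]),
               gamma = unname(r$best_hyperparameters["gamma"]),
               cv_accuracy = r$cv_accuracy, test_accuracy = r$test_accuracy,
               stringsAsFactors = FALSE)))
  rownames(summary) <- NULL
  structure(list(reports = reports, summary = summary, config = config),
            class = "progression_experiment")
}

#' @export
print.progression_experiment <- function(x, ...) {
  cat("Progression classification experiment (", nrow(x$summary),
      " cells)\n", sep = "")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}
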