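test_that("the 0.8/0.2 split is deterministic, sized and stratified", {
  ids <- sprintf("s%03d", 1:135)
  labels <- rep(c("p", "n"), c(73, 62))
  sp <- split_train_test(ids, labels, seed = 4)
  expect_length(sp$test_ids, 27)  # round(0.2 * 135)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  expect_identical(sp, split_train_test(ids, labels, seed = 4))
  # stratification: test-class counts within 1 of 0.2 x each class
  te_lab <- labels[match(sp$test_ids, ids)]
  expect_lte(abs(sum(te_lab == "p") - 0.2 * 73), 1)
  expect_lte(abs(sum(te_lab == "n") - 0.2 * 62), 1)
  expect_error(split_train_test(ids[1:5], labels[1:5]),
               class = "thinpatch_validation_error")
})

test_that("an unstratified split can empty a class from training, and errors", {
  ids <- sprintf("s%02d", 1:12)
  labels <- c("p", rep("n", 11))  # one positive subject
  hit <- FALSE
  for (seed in 1:200) {
    res <- tryCatch(split_train_test(ids, labels, test_fraction = 0.25,
                                     stratified = FALSE, seed = seed),
                    error = function(e) e)
    if (inherits(res, "thinpatch_split_error")) { hit <- TRUE; break }
  }
  expect_true(hit)
  # stratified splitting keeps the lone positive in training
  sp <- split_train_test(ids, labels, test_fraction = 0.25, seed = 1)
  expect_true(ids[1] %in% sp$train_ids)
})

test_that("feature selection matches a brute-force |t| ranking oracle", {
  withr::with_seed(12, {
    x <- matrix(rnorm(60 * 200), 60, 200)
    y <- factor(rep(c("a", "b"), each = 30))
  })
  sel <- select_features(x, y, k = 30)
  tstats <- vapply(seq_len(ncol(x)), function(j)
    abs(stats::t.test(x[y == "a", j], x[y == "b", j],
                      var.equal = TRUE)$statistic), numeric(1))
  brute <- sort(order(-tstats, seq_along(tstats))[1:30])
  expect_identical(sel$indices, as.integer(brute))
  # a perfectly separating feature dominates at k = 1
  x[, 77] <- ifelse(y == "a", 0, 10) + rnorm(60, 0, 0.01)
  expect_identical(select_features(x, y, k = 1)$indices, 77L)
  # zero-variance features rank last
  x[, 1] <- 0
  expect_false(1L %in% select_features(x, y, k = 199)$indices)
  expect_error(select_features(x, y, k = 300),
               class = "thinpatch_config_error")
})

test_that("grid search tunes on CV accuracy with smallest-C/gamma tie-break", {
  bl <- make_blobs(n_per = 30, sep = 4, seed = 9)
  cfg <- classifier_config(c_grid = c(0.1, 1, 10), gamma_grid = c(0.1, 1),
                           seed = 1)
  tuned <- tune_svm(bl$x, bl$y, cfg, seed = 2)
  expect_gte(max(tuned$grid$cv_accuracy), 0.95)
  # the reported winner is the first maximum in (C, gamma) order
  g <- tuned$grid
  first_max <- g[which.max(g$cv_accuracy), ]
  expect_equal(unname(tuned$best_hyperparameters["C"]), first_max$C)
  expect_equal(unname(tuned$best_hyperparameters["gamma"]), first_max$gamma)
  expect_true(all(g$C == sort(g$C)))  # ordered by C then gamma
  # shuffled labels stay near the majority rate
  y_perm <- withr::with_seed(3, sample(bl$y))
  null_tuned <- tune_svm(bl$x, y_perm, cfg, seed = 2)
  expect_lte(null_tuned$cv_accuracy, 0.5 + 3 * sqrt(0.25 / 60) + 0.1)
})

test_that("accuracy is the plain fraction of correct test predictions", {
  bl <- make_blobs(n_per = 13, sep = 0, seed = 10)  # pure noise
  m <- svm_fit(bl$x, bl$y, cost = 1, gamma = 0.5)
  ev <- evaluate_classifier(m, bl$x, bl$y)
  expect_equal(ev$test_accuracy, mean(ev$predictions$correct))
  expect_equal(nrow(ev$predictions), 26)
  expect_error(evaluate_classifier(m, bl$x[0, ], factor(character(0))),
               class = "thinpatch_validation_error")
})

test_that("feature selection and tuning never touch held-out labels", {
  st <- small_study()
  m <- small_map()
  lab <- label_progressors(st$patients$clinical, "extremity", "Y1")
  y <- factor(ifelse(lab$progressor, "p", "n"))
  sp <- split_train_test(lab$subject_id, y, seed = 6)
  tr <- match(sp$train_ids, lab$subject_id)
  x_tr <- m$z[sp$train_ids, , drop = FALSE]
  cfg <- classifier_config(n_features = 20, c_grid = c(0.1, 1),
                           gamma_grid = c(0.01, 0.1))
  sel1 <- select_features(x_tr, y[tr], k = 20)
  fit1 <- tune_svm(x_tr[, sel1$indices], y[tr], cfg, seed = 6)
  # perturb every held-out label; training artifacts must be bit-identical
  y2 <- y
  te <- match(sp$test_ids, lab$subject_id)
  y2[te] <- rev(y2[te])
  sel2 <- select_features(x_tr, y2[tr], k = 20)
  fit2 <- tune_svm(x_tr[, sel2$indices], y2[tr], cfg, seed = 6)
  expect_identical(sel1$indices, sel2$indices)
  expect_identical(fit1$model$coefs, fit2$model$coefs)
  expect_identical(fit1$model$b, fit2$model$b)
  expect_identical(fit1$best_hyperparameters, fit2$best_hyperparameters)
})

test_that("the full experiment produces 12 coherent, reproducible cells", {
  st <- small_study()
  m <- small_map()
  roi <- patch_set(st$config$roi_patches, name = "roi")
  cfg <- classifier_config(n_features = length(roi$indices),
                           c_grid = c(0.1, 1), gamma_grid = c(0.01, 0.1),
                           seed = 2)
  ex <- run_progression_experiment(m, st$patients$clinical, roi, cfg)
  expect_equal(nrow(ex$summary), 12)
  expect_setequal(unique(ex$summary$outcome),
                  c("extremity", "total_motor", "cognitive"))
  for (r in ex$reports) {
    expect_length(r$selected_patches$indices, length(roi$indices))
    expect_length(intersect(r$train_ids, r$test_ids), 0)
    expect_true(r$test_accuracy >= 0 && r$test_accuracy <= 1)
    if (r$feature_mode == "restricted_roi")
      expect_identical(r$selected_patches$indices, roi$indices)
  }
  # same split within a (measure, horizon) cell, across feature modes
  expect_identical(ex$reports$extremity.Y1.restricted_roi$test_ids,
                   ex$reports$extremity.Y1.wholebrain_selected$test_ids)
  ex2 <- run_progression_experiment(m, st$patients$clinical, roi, cfg)
  expect_identical(ex$summary, ex2$summary)
})
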