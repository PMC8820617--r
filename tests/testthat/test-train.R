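small_grid <- function(p) {
  default_hyper_grid(p, ntree = c(50, 100), mtry = c(3, 5),
                     cost = c(0.25, 2, 16), sigma_mult = 1)
}

test_that("mtry upper bound follows the square-root rule", {
  expect_equal(mtry_upper_bound(177), 13L)
  expect_equal(mtry_upper_bound(100), 10L)
  expect_equal(mtry_upper_bound(1), 1L)
  expect_equal(mtry_upper_bound(2), 1L) # floor + clamp
  expect_error(mtry_upper_bound(0), ">= 1")
})

test_that("default grids match the reference ranges", {
  g <- default_hyper_grid(177)
  expect_true(all(g$rf$ntree >= 25 & g$rf$ntree <= 500))
  expect_equal(range(g$rf$mtry), c(5L, 13L))
  # ten cost values, powers of two from 2^-2 to 2^7
  expect_equal(g$svm$cost, 2^(-2:7))
  expect_length(g$svm$cost, 10L)
  expect_equal(range(g$svm$cost), c(0.25, 128))
})

test_that("hyperparameter scan picks by accuracy with deterministic tie-breaks", {
  fx <- make_fixture(30, 10, effect = 3, seed = 21)
  g <- default_hyper_grid(15, ntree = c(50, 100), mtry = c(3))
  scan <- scan_rf_hyperparams(fx$matrix, fx$labels, g, cv_control(5, 2), seed = 8)
  expect_equal(nrow(scan$table), 2L)
  expect_equal(scan$table$n_folds, rep(10L, 2))
  expect_true(all(scan$table$mean_accuracy >= 0 & scan$table$mean_accuracy <= 1))
  # determinism
  scan2 <- scan_rf_hyperparams(fx$matrix, fx$labels, g, cv_control(5, 2), seed = 8)
  expect_identical(scan$table, scan2$table)
  # ties (here accuracy is saturated at 1) go to the smaller ntree
  if (scan$table$mean_accuracy[1] == scan$table$mean_accuracy[2]) {
    expect_equal(scan$winner$ntree, 50L)
  }
  # single-class input fails stratification
  one_class <- fx$labels
  one_class[] <- "inhibitor"
  expect_error(scan_rf_hyperparams(fx$matrix, one_class, g, cv_control(5, 1), 1),
               "stratification")
})

test_that("mean Gini importance ranks planted descriptors first", {
  fx <- make_fixture(50, 30, effect = 2, seed = 13)
  imp <- mean_gini_importance(fx$matrix, fx$labels,
                              params = list(ntree = 50), n_runs = 30, seed = 5)
  expect_equal(nrow(imp), 35L)
  expect_true(all(imp$importance >= 0))
  top5 <- tidy(imp)$descriptor[1:5]
  expect_setequal(top5, paste0("inf.", 1:5))

  # n_runs = 1 equals a single forest at the derived seed
  one <- mean_gini_importance(fx$matrix, fx$labels,
                              params = list(ntree = 50, mtry = 5),
                              n_runs = 1, seed = 17)
  single <- ranger::ranger(
    x = as.matrix(fx$matrix[, -1]), y = fx$labels, num.trees = 50, mtry = 5,
    importance = "impurity", seed = 17 + 1, num.threads = 1
  )$variable.importance
  expect_equal(sort(one$importance, decreasing = TRUE),
               unname(sort(single, decreasing = TRUE)))
  expect_error(mean_gini_importance(fx$matrix, fx$labels, n_runs = 0), "n_runs")
})

test_that("importance on pure noise is flat", {
  spec <- fixture_spec(n_active = 50, n_inactive = 50, n_informative = 0,
                       n_noise = 30, effect_size = 0, seed = 23)
  fx <- gen_descriptor_table(spec)
  imp <- mean_gini_importance(fx$matrix, fx$labels,
                              params = list(ntree = 50), n_runs = 50, seed = 1)
  expect_lt(max(imp$importance) / median(imp$importance), 3)
})

test_that("descriptor selection supports top-k and threshold modes", {
  prof <- tibble::tibble(descriptor = c("a", "b", "c"), importance = c(5, 3, 1))
  expect_equal(select_descriptors(prof, top_k = 2), c("a", "b"))
  expect_equal(select_descriptors(prof, above_threshold = 2), c("a", "b"))
  expect_error(select_descriptors(prof, top_k = 4), "exceeds")
  expect_error(select_descriptors(prof), "exactly one")
  # ties at the k-th rank break alphabetically
  tied <- tibble::tibble(descriptor = c("z", "m", "a"), importance = c(9, 1, 1))
  expect_equal(select_descriptors(tied, top_k = 2), c("z", "a"))
})

test_that("trained forest bundle predicts accurately and reproducibly", {
  fx <- make_fixture(40, 15, effect = 3, seed = 31)
  rf <- train_rf(fx$matrix, fx$labels, small_grid(20), cv_control(5, 2), seed = 6)
  expect_s3_class(rf, "cyp_model")
  expect_gte(rf$cv_result$winner$mean_accuracy, 0.95)
  # resubstitution accuracy at least the CV mean (optimism)
  resub_acc <- mean(rf$resub$.pred_label == as.character(fx$labels))
  expect_gte(resub_acc, rf$cv_result$winner$mean_accuracy - 1e-9)

  rf2 <- train_rf(fx$matrix, fx$labels, small_grid(20), cv_control(5, 2), seed = 6)
  expect_identical(predict(rf2, fx$matrix)$.pred_label,
                   predict(rf, fx$matrix)$.pred_label)

  # prediction contract
  p <- predict(rf, fx$matrix)
  expect_equal(p$.pred_label, rf$resub$.pred_label)
  extra <- dplyr::mutate(fx$matrix, irrelevant = 1)
  expect_equal(predict(rf, extra)$.pred_label, p$.pred_label)
  expect_error(predict(rf, fx$matrix[, -2]), names(fx$matrix)[2])
  expect_true(all(p$.pred_score >= 0 & p$.pred_score <= 1))
})

test_that("SVM bundle requires scaling, tunes cost, and stores the link", {
  fx <- make_fixture(40, 15, effect = 3, seed = 37)
  st <- standardize(fx$matrix)
  expect_error(train_svm_rbf(fx$matrix, fx$labels, st$params,
                             small_grid(20), cv_control(5, 1), 1),
               "not standardized")
  svm <- train_svm_rbf(st$matrix, fx$labels, st$params, small_grid(20),
                       cv_control(5, 2), seed = 6)
  expect_gte(svm$cv_result$winner$mean_accuracy, 0.95)
  expect_equal(nrow(svm$cv_result$table), 3L)
  # raw-scale prediction applies the stored scaling internally
  p_raw <- predict(svm, fx$matrix)
  expect_equal(p_raw$.pred_label, svm$resub$.pred_label)
  svm2 <- train_svm_rbf(st$matrix, fx$labels, st$params, small_grid(20),
                        cv_control(5, 2), seed = 6)
  expect_identical(glance(svm2)$cost, glance(svm)$cost)
  expect_identical(predict(svm2, fx$matrix)$.pred_label, p_raw$.pred_label)
})

test_that("bundles round-trip serialization bit-for-bit", {
  fx <- make_fixture(30, 10, effect = 3, seed = 41)
  rf <- train_rf(fx$matrix, fx$labels, small_grid(15), cv_control(5, 1), seed = 2)
  path <- tempfile(fileext = ".rds")
  save_model(rf, path)
  back <- load_model(path)
  expect_identical(predict(back, fx$matrix)$.pred_label,
                   predict(rf, fx$matrix)$.pred_label)
  # version guard
  broken <- rf
  broken$version <- 99L
  save_model(broken, path)
  expect_error(load_model(path), "version")
})

test_that("importance rankings converge across disjoint run batches", {
  fx <- make_fixture(60, 30, effect = 1.5, seed = 53)
  hits <- 0L
  trials <- 5L
  for (t in seq_len(trials)) {
    a <- mean_gini_importance(fx$matrix, fx$labels, params = list(ntree = 50),
                              n_runs = 40, seed = 1000 * t)
    b <- mean_gini_importance(fx$matrix, fx$labels, params = list(ntree = 50),
                              n_runs = 40, seed = 1000 * t + 500)
    if (setequal(tidy(a)$descriptor[1:5], tidy(b)$descriptor[1:5])) hits <- hits + 1L
  }
  expect_gte(hits, trials - 1L)
})

test_that("random-forest importance agrees with an independent implementation", {
  skip_if_not_installed("randomForest")
  fx <- make_fixture(50, 20, effect = 2, seed = 61)
  imp <- mean_gini_importance(fx$matrix, fx$labels, params = list(ntree = 200),
                              n_runs = 10, seed = 3)
  set.seed(3)
  ref <- randomForest::randomForest(
    x = as.data.frame(fx$matrix[, -1]), y = fx$labels, ntree = 500,
    importance = FALSE
  )$importance[, "MeanDecreaseGini"]
  ref_tbl <- tibble::tibble(descriptor = names(ref), ref = unname(ref))
  joined <- dplyr::inner_join(tibble::as_tibble(imp), ref_tbl, by = "descriptor")
  expect_gt(cor(joined$importance, joined$ref, method = "spearman"), 0.7)
})
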