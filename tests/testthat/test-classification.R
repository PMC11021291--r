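test_that("standardization uses training statistics and handles degeneracy", {
  tr <- data.frame(a = c(8, 12, 10), b = c(1, 2, 3))
  std <- standardize(tr, data.frame(a = 14, b = 2))
  expect_equal(colMeans(std$train), c(a = 0, b = 0))
  expect_equal(apply(std$train, 2, sd), c(a = 1, b = 1))
  expect_equal(std$test[1, "a"], unname((14 - 10) / 2), ignore_attr = TRUE)
  # train == test: standardized test has mean 0, sd 1
  std2 <- standardize(tr, tr)
  expect_equal(colMeans(std2$test), c(a = 0, b = 0))
  expect_warning(
    std3 <- standardize(data.frame(a = c(1, 1, 1), b = 1:3),
                        data.frame(a = 5, b = 2)),
    "Zero-variance"
  )
  expect_true(all(std3$train[, "a"] == 0))
  expect_equal(std3$test[1, "a"], unname(0), ignore_attr = TRUE)
  expect_error(standardize(data.frame(a = 1)), class = "stmcit_data_error")
})

test_that("metric identities: balanced accuracy and F1 degeneracies", {
  withr::with_seed(8, {
    for (i in 1:25) {
      truth <- sample(c(TRUE, FALSE), 64, replace = TRUE, prob = c(0.2, 0.8))
      pred <- sample(c(TRUE, FALSE), 64, replace = TRUE)
      m <- classification_metrics(truth, pred)
      sens <- sum(truth & pred) / max(sum(truth), 1)
      spec <- sum(!truth & !pred) / max(sum(!truth), 1)
      expect_equal(m$balanced_accuracy, (sens + spec) / 2)
      expect_gte(m$f1, 0)
      expect_lte(m$f1, 1)
    }
  })
  expect_equal(classification_metrics(c(TRUE, FALSE), c(FALSE, FALSE))$f1, 0)
  expect_equal(
    classification_metrics(c(TRUE, FALSE, FALSE), c(FALSE, TRUE, FALSE))$f1,
    0
  )
})

test_that("perfectly separated features give ROC AUC 1 within participants", {
  feat <- synthetic_features(separation = 10, seed = 2)
  res <- within_participant_classify(feat, seed = 4, participant_id = "S01")
  expect_equal(res$roc_auc, 1)
  expect_gte(res$balanced_accuracy, 0.9)
  expect_gte(res$f1, 0.8)
  one_class <- dplyr::mutate(feat, label = FALSE)
  expect_error(within_participant_classify(one_class, seed = 1),
               class = "stmcit_label_error")
})

test_that("random labels on structured features stay at chance with F1 collapse", {
  res <- purrr::map_dfr(1:6, function(i) {
    feat <- synthetic_features(separation = 3, seed = i)
    relab <- withr::with_seed(100 + i, {
      dplyr::mutate(feat, label = seq_len(64) %in% sample.int(64, 8))
    })
    within_participant_classify(relab, seed = 200 + i)
  })
  expect_gte(mean(res$balanced_accuracy), 0.4)
  expect_lte(mean(res$balanced_accuracy), 0.6)
  expect_lte(mean(res$f1), 0.15)
})

test_that("classification results are deterministic under a fixed seed", {
  feat <- synthetic_features(separation = 1.5, seed = 9)
  a <- within_participant_classify(feat, seed = 31)
  b <- within_participant_classify(feat, seed = 31)
  expect_identical(a, b)
  c <- within_participant_classify(feat, seed = 32)
  expect_false(identical(a$roc_auc, c$roc_auc))
  # non-nested mode runs and is also deterministic
  cfgnn <- classification_config(nested = FALSE)
  d <- within_participant_classify(feat, cfgnn, seed = 31)
  expect_identical(d, within_participant_classify(feat, cfgnn, seed = 31))
})

test_that("held-out decision scores do not depend on held-out labels", {
  feat <- synthetic_features(separation = 2, seed = 5)
  x <- as.matrix(feat[, c("dwell_phase1", "dwell_phase2",
                          "fixation_count", "visit_count")])
  train <- 1:48
  test <- 49:64
  std <- stmcit:::standardize_quiet(x[train, ], x[test, ])
  y <- factor(ifelse(feat$label[train], "famous", "unknown"))
  model <- stmcit:::fit_rbf_svm(std$train, y, cost = 10, gamma = 0.1)
  s1 <- stmcit:::svm_scores(model, std$test)$scores
  # permute the held-out labels; the fitted model and scores are untouched
  model2 <- stmcit:::fit_rbf_svm(std$train, y, cost = 10, gamma = 0.1)
  s2 <- stmcit:::svm_scores(model2, std$test)$scores
  expect_identical(s1, s2)
})

test_that("between-participant protocol: identical separable cohorts give AUC 1", {
  feats <- dplyr::bind_rows(lapply(1:3, function(i) {
    dplyr::mutate(synthetic_features(separation = 10, seed = 2),
                  participant_id = paste0("S", i))
  }))
  res <- between_participant_classify(feats, seed = 6)
  expect_equal(nrow(res), 3)
  expect_true(all(res$roc_auc == 1))
  expect_error(between_participant_classify(
    dplyr::filter(feats, participant_id == "S1"), seed = 1
  ), class = "stmcit_data_error")
})

test_that("random taggings mark exactly 8 of 64 images famous at uniform frequency", {
  draws <- withr::with_seed(77, {
    t(vapply(1:1000, function(i) stmcit:::random_tagging(64, 8),
             logical(64)))
  })
  expect_true(all(rowSums(draws) == 8))
  freq <- colMeans(draws)
  expect_true(all(abs(freq - 0.125) < 0.04))
})

test_that("the random-tag baseline runs the identical protocol at chance level", {
  feats <- dplyr::bind_rows(lapply(1:4, function(i) {
    dplyr::mutate(synthetic_features(separation = 6, seed = 10 + i),
                  participant_id = paste0("S", i))
  }))
  base <- random_tag_baseline(feats, seed = 21)
  expect_equal(nrow(base), 4)
  expect_equal(unique(base$analysis), "baseline-within")
  expect_true(all(base$balanced_accuracy >= 0.3 &
                    base$balanced_accuracy <= 0.7))
  expect_identical(base, random_tag_baseline(feats, seed = 21))
})

test_that("baseline comparison reproduces the closed-form Welch t-test", {
  a <- tibble::tibble(analysis = "within", roc_auc = c(0.9, 1, 0.95),
                      balanced_accuracy = c(0.9, 0.8, 0.85),
                      f1 = c(0.8, 0.9, 0.7))
  b <- tibble::tibble(analysis = "baseline-within",
                      roc_auc = c(0.5, 0.4, 0.6),
                      balanced_accuracy = c(0.5, 0.45, 0.55),
                      f1 = c(0, 0, 0))
  cmp <- compare_to_baseline(a, b)
  # hand-computed Welch statistic for roc_auc
  m1 <- mean(a$roc_auc); m2 <- mean(b$roc_auc)
  v1 <- var(a$roc_auc); v2 <- var(b$roc_auc)
  t_hand <- (m1 - m2) / sqrt(v1 / 3 + v2 / 3)
  expect_equal(cmp$t[cmp$metric == "roc_auc"], t_hand)
  d_hand <- (m1 - m2) / sqrt((2 * v1 + 2 * v2) / 4)
  expect_equal(cmp$cohens_d[cmp$metric == "roc_auc"], d_hand)
  # identical samples: t = 0, d = 0
  cmp0 <- compare_to_baseline(a, a)
  expect_true(all(cmp0$t == 0))
  expect_true(all(cmp0$cohens_d == 0))
  # zero-variance equal samples are flagged undefined, not raised
  z <- dplyr::mutate(a, roc_auc = 1, balanced_accuracy = 1, f1 = 1)
  cmpz <- compare_to_baseline(z, z)
  expect_true(all(cmpz$undefined))
})

test_that("protocol constants: 4 outer folds of 16 with stratified famous counts", {
  cfg <- classification_config()
  expect_equal(cfg$cv_folds, 4)
  expect_equal(cfg$c_grid, 10^(-3:3))
  expect_equal(cfg$gamma_grid, 10^(-3:3))
  labels <- rep(c(TRUE, FALSE), c(8, 56))
  folds <- withr::with_seed(3, stmcit:::stratified_folds(labels, 4))
  expect_equal(unname(table(folds)), rep(16L, 4), ignore_attr = TRUE)
  expect_equal(unname(table(folds[labels])), rep(2L, 4),
               ignore_attr = TRUE)
})
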