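test_that("metrics reproduce hand-derived values from confusion counts", {
  cc <- structure(c(TP = 42L, FP = 10L, FN = 11L, TN = 42L),
                  class = "confusion_counts")
  m <- classification_metrics(cc)
  expect_equal(round(unname(m[c("Sn", "Sp", "Acc", "F", "MCC")]), 3),
               c(0.792, 0.808, 0.800, 0.800, 0.600))

  perfect <- classification_metrics(c(TP = 50, FP = 0, FN = 0, TN = 50))
  expect_equal(unname(perfect), rep(1, 5))

  degenerate <- classification_metrics(c(TP = 0, FP = 0, FN = 10, TN = 10))
  expect_equal(unname(degenerate[c("Sn", "F", "MCC")]), c(0, 0, 0))
  expect_equal(unname(degenerate[["Sp"]]), 1)
})

test_that("MCC magnitude is symmetric under simultaneous class swap", {
  withr::with_seed(31, {
    for (i in 1:25) {
      truth <- rbinom(40, 1, 0.5)
      pred <- rbinom(40, 1, 0.5)
      m1 <- classification_metrics(confusion_counts(truth, pred))
      m2 <- classification_metrics(confusion_counts(1L - truth, 1L - pred))
      expect_equal(abs(m1[["MCC"]]), abs(m2[["MCC"]]), tolerance = 1e-12)
    }
  })
})

test_that("AUC equals the normalized Mann-Whitney U on random score vectors", {
  expect_equal(as.numeric(auc_score(c(1, 1, 0, 0), c(1, 1, 0, 0))), 1)
  expect_equal(as.numeric(auc_score(c(1, 0, 1, 0), rep(0.3, 4))), 0.5)
  expect_equal(as.numeric(auc_score(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1))),
               naive_auc(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1)))

  withr::with_seed(77, {
    for (i in 1:100) {
      n <- sample(6:30, 1)
      labels <- c(1L, 0L, rbinom(n - 2, 1, 0.5))  # both classes guaranteed
      scores <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties
      expect_equal(as.numeric(auc_score(labels, scores)),
                   naive_auc(labels, scores), tolerance = 1e-10)
    }
  })
  expect_error(auc_score(rep(1L, 5), runif(5)), "both classes")
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(15, {
    labels <- rbinom(60, 1, 0.4)
    labels[1:2] <- c(0L, 1L)
    scores <- runif(60) + 0.5 * labels
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(as.numeric(auc_score(labels, scores)), ref,
                 tolerance = 1e-10)
  })
})

test_that("forest training is seeded-deterministic and checks its inputs", {
  fm <- toy_feature_matrix(n_pos = 30, n_neg = 30, seed = 5)
  model <- train_forest(fm, trees = 80, seed = 21)
  again <- train_forest(fm, trees = 80, seed = 21)
  probe <- toy_feature_matrix(n_pos = 10, n_neg = 10, seed = 6)
  expect_identical(predict_forest(model, probe)$score,
                   predict_forest(again, probe)$score)

  # linearly separable toy: training accuracy 1
  sep <- feature_matrix(
    matrix(c(1:10, 31:40, rep(0, 20)), ncol = 2,
           dimnames = list(paste0("s", 1:20), c("f1", "f2"))),
    rep(c(0L, 1L), each = 10))
  m <- train_forest(sep, trees = 50, seed = 1)
  expect_equal(predict_forest(m, sep)$class, sep$labels)

  expect_error(train_forest(fm, subset = c("sig1", "ghost")), "ghost")
  expect_error(train_forest(feature_matrix(fm$x, rep(1L, nrow(fm$x)))),
               "both classes")
  # prediction refuses a matrix missing a training feature
  expect_error(predict_forest(model, fm_subset(fm, features = "sig1")),
               "missing")
})

test_that("evaluate ties metrics to confusion counts and the Acc identity", {
  fm <- toy_feature_matrix(n_pos = 30, n_neg = 50, seed = 9)
  model <- train_forest(fm, trees = 80, seed = 3)
  test <- toy_feature_matrix(n_pos = 15, n_neg = 25, seed = 10)
  rep <- evaluate(model, test)
  cc <- rep$confusion
  expect_equal(sum(cc), nrow(test$x))
  expect_equal(rep$metrics[["Acc"]],
               (cc[["TP"]] + cc[["TN"]]) / sum(cc))
  m <- classification_metrics(cc)
  expect_equal(rep$metrics[names(m)], m)
  expect_true(all(rep$metrics[c("Sn", "Sp", "Acc", "F", "AUC")] >= 0 &
                  rep$metrics[c("Sn", "Sp", "Acc", "F", "AUC")] <= 1))
  expect_true(rep$metrics[["MCC"]] >= -1 && rep$metrics[["MCC"]] <= 1)
  expect_error(evaluate(model, feature_matrix(test$x)), "labeled")
})

test_that("stratified cross-validation preserves fold sizes and class ratios", {
  fm <- toy_feature_matrix(n_pos = 40, n_neg = 60, seed = 12)
  cv <- cross_validate(fm, folds = 10, trees = 50, seed = 17)
  tab <- table(cv$fold_id)
  expect_equal(as.integer(tab), rep(10L, 10))  # 100 samples, 10 per fold
  for (f in 1:10) {
    expect_equal(sum(fm$labels[cv$fold_id == f] == 1L), 4L)  # exact here
  }
  expect_equal(sum(cv$pooled_confusion), 100)
  expect_length(cv$fold_reports, 10)
  # strong signal: high mean CV accuracy
  expect_gt(cv$mean_metrics[["Acc"]], 0.9)
  expect_error(cross_validate(fm, folds = 50), "fewer samples")
})

test_that("group feature means expose class-conditional enrichment", {
  x <- cbind(const = rep(0.2, 6),
             up = c(0.4, 0.4, 0.4, 0.1, 0.1, 0.1))
  rownames(x) <- paste0("s", 1:6)
  fm <- feature_matrix(x, rep(c(1L, 0L), each = 3))
  gm <- group_feature_means(fm)
  expect_equal(gm$difference[gm$feature == "const"], 0)
  expect_equal(gm$difference[gm$feature == "up"], 0.3)
  expect_error(group_feature_means(feature_matrix(x, rep(1L, 6))),
               "both classes")
})

test_that("positives enriched in hydrophobic triads show positive CT differences", {
  spec <- synthetic_spec(60, 60, length_range = c(80, 150), enrichment = 3,
                         seed = 44)
  fm <- extract_features(generate_sequences(spec))
  # triads drawn only from classes 1-2 (hydrophobic A,G,V,I,L,F,P)
  hydro_triads <- paste("CT", rep(1:2, each = 4), rep(rep(1:2, each = 2), 2),
                        rep(1:2, 4), sep = ".")
  gm <- group_feature_means(fm, features = hydro_triads)
  expect_gt(mean(gm$difference > 0), 0.75)
})
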