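test_that("confusion metrics match the forced arithmetic and conventions", {
  y <- c(rep("D", 4), rep("NotD", 6))
  p <- c("D", "D", "D", "NotD", "D", rep("NotD", 5)) # TP3 FN1 FP1 TN5
  cm <- confusion_metrics(y, p)
  expect_equal(cm$precision, 0.75)
  expect_equal(cm$recall, 0.75)
  expect_equal(cm$f1, 0.75)
  expect_equal(cm$accuracy, 0.8)

  perfect <- confusion_metrics(y, y)
  expect_true(all(unlist(perfect) == 1))

  none_pos <- confusion_metrics(y, rep("NotD", 10))
  expect_equal(none_pos$precision, 0)
  expect_equal(none_pos$f1, 0)

  expect_error(confusion_metrics(character(0), character(0)),
               class = "phenodes_empty_error")
})

test_that("f1 is the harmonic mean of its own precision and recall", {
  phenodes:::with_seed(5, {
    for (i in 1:50) {
      n <- sample(10:60, 1)
      y <- sample(c("D", "NotD"), n, replace = TRUE)
      p <- sample(c("D", "NotD"), n, replace = TRUE)
      if (length(unique(y)) < 2) next
      cm <- confusion_metrics(y, p)
      if (cm$precision + cm$recall > 0) {
        expect_equal(cm$f1,
                     2 * cm$precision * cm$recall / (cm$precision + cm$recall),
                     tolerance = 1e-9)
      }
      expect_true(all(unlist(cm) >= 0 & unlist(cm) <= 1))
    }
  })
})

test_that("ROC AUC handles separation, ties, and matches pair counting exactly", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.4, 0.3))$auc, 1)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.5, 4))$auc, 0.5)
  expect_error(roc_auc(rep("D", 4), runif(4)), "both classes")

  phenodes:::with_seed(6, {
    for (i in 1:500) {
      n <- sample(6:30, 1)
      y <- sample(c(0, 1), n, replace = TRUE)
      if (length(unique(y)) < 2) next
      s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE) # many ties
      expect_equal(roc_auc(y, s)$auc, oracle_auc(y, s), tolerance = 1e-12)
    }
  })
})

test_that("cross-validated evaluation is deterministic and detects strong signal", {
  tab <- generate_table(synthetic_config(n_samples = 120, n_features = 40,
                                         n_informative = 5, effect = 4,
                                         imbalance = 0.4, seed = 31))
  comp <- to_relative(tab, 1)
  y <- tab$labels
  X <- clr_transform(comp)
  # module 2 runs on the feature-selected table: stand in for the consensus
  # stage with the known planted features (feature selection is tested in its
  # own file)
  feats <- attr(tab, "informative_features")
  tuned <- lapply(c("knn", "random_forest"), function(fam) {
    grid_tune(classifier_spec(fam, default_grids(TRUE)[[fam]]),
              X[, feats], y, folds = 5, seed = 32)
  })
  m1 <- cv_evaluate(comp, y, tuned, rules = c("desp", "knorau"), folds = 5,
                    seed = 33, augment_strategy = "augment",
                    feature_subset = feats)
  m2 <- cv_evaluate(comp, y, tuned, rules = c("desp", "knorau"), folds = 5,
                    seed = 33, augment_strategy = "augment",
                    feature_subset = feats)
  expect_identical(m1, m2)
  des_auc <- m1$roc_auc[m1$model %in% c("desp", "knorau")]
  expect_true(all(des_auc >= 0.95))
})

test_that("label-permuted data yields chance-level cross-validated AUC", {
  tab <- generate_table(synthetic_config(n_samples = 300, n_features = 40,
                                         n_informative = 5, effect = 0,
                                         seed = 41))
  comp <- to_relative(tab, 1)
  y <- tab$labels
  X <- clr_transform(comp)
  tuned <- list(grid_tune(classifier_spec("knn", default_grids(TRUE)$knn),
                          X, y, folds = 5, seed = 42))
  tuned[[2]] <- grid_tune(classifier_spec("svm", default_grids(TRUE)$svm),
                          X, y, folds = 5, seed = 42)
  m <- cv_evaluate(comp, y, tuned, rules = "desp", folds = 10, seed = 43)
  expect_true(all(m$roc_auc > 0.4 & m$roc_auc < 0.6))
})

test_that("averaging over NSF matches hand-computed means and skips absent cells", {
  metrics <- data.frame(
    model = rep(c("a", "b"), each = 3),
    split = "test",
    nsf = c(2, 3, 4, 2, 3, 4),
    f1 = c(0.5, 0.6, 0.7, 0.2, 0.4, 0.6),
    precision = 0.5, recall = 0.5, accuracy = 0.5,
    roc_auc = c(0.8, 0.9, 1.0, 0.6, 0.7, 0.8))
  # model b's nsf = 4 cell is "unattainable": drop it
  metrics <- metrics[-6, ]
  avg <- average_over_nsf(metrics)
  expect_equal(avg$roc_auc[avg$model == "a"], 0.9)
  expect_equal(avg$roc_auc[avg$model == "b"], 0.65)
  expect_equal(avg$n_nsf[avg$model == "b"], 2)

  one <- average_over_nsf(metrics[1, ])
  expect_equal(one$f1, 0.5)
  expect_equal(one$n_nsf, 1)
})

test_that("the AUC-vs-NSF plot builds", {
  metrics <- data.frame(model = rep(c("a", "b"), each = 2), split = "test",
                        nsf = c(2, 3, 2, 3), roc_auc = c(.8, .9, .7, .75))
  gg <- plot_auc_vs_nsf(metrics)
  expect_s3_class(gg, "ggplot")
})
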