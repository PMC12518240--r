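#' Confusion-table metrics
#'
#' F1, precision, recall and accuracy from the 2x2 confusion table with `"D"`
#' as the positive class. Zero-denominator conventions: precision, recall and
#' F1 are 0 when undefined.
#'
#' @param labels true labels (`"D"`/`"NotD"`).
#' @param predicted predicted labels.
#' @return named list: `f1`, `precision`, `recall`, `accuracy`.
#' @export
confusion_metrics <- function(labels, predicted) {
  assert_that(length(labels) > 0, "empty input", class = "phenodes_empty_error")
  assert_that(length(labels) == length(predicted), "length mismatch")
  y <- as_pheno_factor(labels)
  p <- as_pheno_factor(predicted)
  tp <- sum(y == "D" & p == "D")
  fp <- sum(y == "NotD" & p == "D")
  fn <- sum(y == "D" & p == "NotD")
  tn <- sum(y == "NotD" & p == "NotD")
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(f1 = f1, precision = precision, recall = recall,
       accuracy = (tp + tn) / length(y))
}

#' Empirical ROC curve and AUC
#'
#' Trapezoidal area under the empirical ROC curve; tied scores step the curve
#' simultaneously, which is equivalent to the Mann-Whitney statistic with 0.5
#' credit per tied (positive, negative) pair.
#'
#' @param labels true labels (`"D"` positive).
#' @param scores numeric scores (higher = more "D").
#' @return list with `auc` and `curve` (data.frame of `fpr`, `tpr` at each
#'   distinct threshold).
#' @export
roc_auc <- function(labels, scores) {
  y <- label01(labels)
  assert_that(length(y) == length(scores), "length mismatch")
  n_pos <- sum(y == 1)
  n_neg <- sum(y == 0)
  assert_that(n_pos > 0 && n_neg > 0, "both classes required for ROC",
              class = "phenodes_degenerate_error")
  ord <- order(-scores)
  s <- scores[ord]
  yy <- y[ord]
  grp <- cumsum(!duplicated(s)) # simultaneous steps for tied scores
  tp <- tapply(yy, grp, sum)
  fpn <- tapply(1 - yy, grp, sum)
  tpr <- c(0, cumsum(tp) / n_pos)
  fpr <- c(0, cumsum(fpn) / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(auc = as.numeric(auc), curve = data.frame(fpr = fpr, tpr = tpr))
}

#' Cross-validated evaluation of base models and DES ensembles
#'
#' Stratified k-fold cross-validation over the training rows. Per fold: the
#' optional augmentation is re-planned on the fold-train part only; base
#' models are fitted on the (augmented) fold-train part; the fold-validation
#' part doubles as the DSEL for the DES rules and receives the out-of-fold
#' predictions. Metrics are computed on the pooled out-of-fold predictions.
#'
#' Augmentation operates in composition space (before CLR): `comp_train` must
#' be the composition matrix; the CLR transform is applied inside each fold
#' after augmenting.
#'
#' @param comp_train composition matrix of the training rows (rows sum to 1).
#' @param y_train training labels.
#' @param tuned list of `tuned_model`s (fitted specs; their `chosen_params`
#'   are reused per fold).
#' @param rules DES rules to evaluate (default all four).
#' @param folds number of folds (default 10).
#' @param seed integer seed.
#' @param augment_strategy `"none"`, `"augment"` or `"downsample"`.
#' @param stratum optional stratum vector for per-stratum balancing.
#' @param k region-of-competence size for the kNN-based rules (default 7).
#' @param p_mask CutMix mask probability.
#' @param feature_subset optional character vector of feature ids: after the
#'   per-fold CLR transform the design matrix is restricted to these columns
#'   (the consensus-selected features).
#' @return data.frame (one row per model/ensemble) with the five metrics, plus
#'   attribute `"scores"`: pooled out-of-fold scores per model.
#' @export
cv_evaluate <- function(comp_train, y_train, tuned, rules = DES_RULES,
                        folds = 10, seed = 1L, augment_strategy = "none",
                        stratum = NULL, k = 7, p_mask = 0.5,
                        feature_subset = NULL) {
  comp_train <- as.matrix(comp_train)
  y_train <- as_pheno_factor(y_train)
  fold_id <- stratified_folds(y_train, folds, derive_seed(seed, "cvfolds"))
  model_names <- c(vapply(tuned, `[[`, "", "family"), rules)
  n <- length(y_train)
  scores <- matrix(NA_real_, n, length(model_names),
                   dimnames = list(NULL, model_names))
  for (f in seq_len(folds)) {
    hold <- fold_id == f
    tr_comp <- comp_train[!hold, , drop = FALSE]
    tr_y <- y_train[!hold]
    tr_strat <- if (!is.null(stratum)) stratum[!hold] else NULL
    if (augment_strategy == "augment") {
      plan <- plan_balancing(tr_y, tr_strat, seed = derive_seed(seed, f))
      aug <- augment(tr_comp, tr_y, plan, stratum = tr_strat, p_mask = p_mask)
      tr_comp <- aug$comp
      tr_y <- aug$labels
    } else if (augment_strategy == "downsample") {
      keep <- downsample_majority(tr_y, tr_strat, seed = derive_seed(seed, f))
      tr_comp <- tr_comp[keep, , drop = FALSE]
      tr_y <- tr_y[keep]
    }
    tr_X <- clr_transform(tr_comp)
    va_X <- clr_transform(comp_train[hold, , drop = FALSE])
    if (!is.null(feature_subset)) {
      tr_X <- tr_X[, feature_subset, drop = FALSE]
      va_X <- va_X[, feature_subset, drop = FALSE]
    }
    va_y <- y_train[hold]
    models <- lapply(tuned, function(tm) {
      fit_classifier(tm$family, tm$chosen_params, tr_X, tr_y,
                     seed = derive_seed(seed, paste0(tm$family, f)))
    })
    for (mi in seq_along(models)) {
      scores[hold, mi] <- predict_proba(models[[mi]], va_X)
    }
    # fold-validation part doubles as DSEL for the DES rules
    pool <- new_model_pool(models, vapply(tuned, `[[`, "", "family"),
                           va_X, va_y)
    for (r in rules) {
      pred <- predict_des(pool, va_X, rule = r, k = k,
                          desc_params = list(seed = derive_seed(seed, paste0(r, f))))
      scores[hold, length(tuned) + match(r, rules)] <- pred$score
    }
  }
  out <- metrics_from_scores(y_train, scores, split = "cv")
  attr(out, "scores") <- scores
  out
}

metrics_from_scores <- function(y, scores, split) {
  rows <- lapply(colnames(scores), function(m) {
    s <- scores[, m]
    pred <- factor(ifelse(s > 0.5, "D", "NotD"), levels = PHENO_LEVELS)
    cm <- confusion_metrics(y, pred)
    data.frame(model = m, split = split, f1 = cm$f1, precision = cm$precision,
               recall = cm$recall, accuracy = cm$accuracy,
               roc_auc = roc_auc(y, s)$auc, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Aggregate metrics across numbers of selected features
#'
#' Averages every metric over NSF per (model, split), mirroring the "averaged
#' over the different numbers of features" summary tables; NSF cells absent
#' because the consensus was unattainable are simply excluded.
#'
#' @param metrics data.frame with columns `model`, `split`, `nsf` and the five
#'   metric columns.
#' @return data.frame of per-(model, split) means plus `n_nsf` (cells
#'   averaged).
#' @export
average_over_nsf <- function(metrics) {
  metric_cols <- c("f1", "precision", "recall", "accuracy", "roc_auc")
  key <- interaction(metrics$model, metrics$split, drop = TRUE)
  rows <- lapply(levels(key), function(kk) {
    sub <- metrics[key == kk, , drop = FALSE]
    out <- data.frame(model = sub$model[1], split = sub$split[1],
                      n_nsf = nrow(sub), stringsAsFactors = FALSE)
    for (mc in metric_cols) out[[mc]] <- mean(sub[[mc]])
    out
  })
  do.call(rbind, rows)
}

#' AUC versus number-of-features plot
#'
#' Line plot of ROC AUC against NSF, one line per model, faceted by split.
#'
#' @param metrics data.frame with columns `model`, `split`, `nsf`, `roc_auc`.
#' @return a ggplot object.
#' @export
plot_auc_vs_nsf <- function(metrics) {
  ggplot2::ggplot(metrics,
                  ggplot2::aes(x = nsf, y = roc_auc, colour = model)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~split) +
    ggplot2::labs(x = "number of selected features (NSF)", y = "ROC AUC") +
    ggplot2::theme_bw()
}
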