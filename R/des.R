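#' Region of competence
#'
#' The k nearest DSEL rows to a query in Euclidean distance (computed on the
#' consensus-selected CLR features). Distance ties are broken by DSEL index,
#' so the region is fully deterministic.
#'
#' @param query numeric vector (one sample in the pool's feature space).
#' @param dsel_X DSEL matrix.
#' @param k region size, `1 <= k <= nrow(dsel_X)`.
#' @return list with `neighbor_idx` (k DSEL row indices, ascending distance),
#'   `distances` and `k`.
#' @export
region_of_competence <- function(query, dsel_X, k) {
  dsel_X <- as.matrix(dsel_X)
  assert_that(k >= 1 && k <= nrow(dsel_X),
              sprintf("k must be in [1, %d]", nrow(dsel_X)))
  d <- sqrt(rowSums(sweep(dsel_X, 2, as.numeric(query))^2))
  ord <- order(d, seq_along(d), method = "radix")[seq_len(k)]
  list(neighbor_idx = ord, distances = d[ord], k = as.integer(k))
}

#' Per-neighbour correctness of the pool on DSEL
#'
#' @param pool a `model_pool`.
#' @return binary matrix (n_models x n_dsel); entry 1 iff the model labels the
#'   DSEL sample correctly.
#' @export
pool_correctness <- function(pool) {
  truth <- as.character(pool$dsel_y)
  t(vapply(pool$models, function(m) {
    as.integer(as.character(predict_label(m, pool$dsel_X)) == truth)
  }, integer(length(truth))))
}

#' DES-P selection
#'
#' Selects the models whose accuracy over the region of competence strictly
#' exceeds the random-classifier rate `1/n_classes`. If none qualifies, falls
#' back to the whole pool (flagged).
#'
#' @param corr binary correctness matrix (n_models x k), columns = region
#'   neighbours.
#' @param n_classes number of classes (2 here).
#' @return list with `selected` (model indices), `weights` (uniform),
#'   `fallback_used`.
#' @export
select_desp <- function(corr, n_classes = 2) {
  corr <- as.matrix(corr)
  competence <- rowMeans(corr) - 1 / n_classes
  sel <- which(competence > 0)
  fallback <- length(sel) == 0
  if (fallback) sel <- seq_len(nrow(corr))
  list(selected = sel, weights = rep(1, length(sel)), fallback_used = fallback)
}

#' KNORA-E selection
#'
#' Selects the models that are correct on every sample of the region; while no
#' model is perfect and k > 1, the farthest neighbour is dropped and the rule
#' retried. If still empty at k = 1, falls back to the whole pool (flagged).
#'
#' @param corr binary correctness matrix (n_models x k_start) with columns
#'   ordered by ascending neighbour distance.
#' @param k_start initial region size (default: all columns).
#' @return list with `selected`, `weights` (uniform), `effective_k`,
#'   `fallback_used`.
#' @export
select_knorae <- function(corr, k_start = ncol(as.matrix(corr))) {
  corr <- as.matrix(corr)
  assert_that(k_start >= 1 && k_start <= ncol(corr), "invalid k_start")
  for (k in seq.int(k_start, 1L)) {
    sel <- which(rowSums(corr[, seq_len(k), drop = FALSE]) == k)
    if (length(sel) > 0) {
      return(list(selected = sel, weights = rep(1, length(sel)),
                  effective_k = k, fallback_used = FALSE))
    }
  }
  list(selected = seq_len(nrow(corr)), weights = rep(1, nrow(corr)),
       effective_k = 0L, fallback_used = TRUE)
}

#' KNORA-U selection
#'
#' Selects the models correct on at least one region sample, weighting each by
#' its number of correct classifications. Falls back to the whole pool with
#' uniform weights if no model is ever correct.
#'
#' @param corr binary correctness matrix (n_models x k).
#' @return list with `selected`, `weights` (correct counts), `fallback_used`.
#' @export
select_knorau <- function(corr) {
  corr <- as.matrix(corr)
  counts <- rowSums(corr)
  sel <- which(counts > 0)
  if (length(sel) == 0) {
    return(list(selected = seq_len(nrow(corr)), weights = rep(1, nrow(corr)),
                fallback_used = TRUE))
  }
  list(selected = sel, weights = counts[sel], fallback_used = FALSE)
}

#' Clustering state for DES-Clustering
#'
#' Partitions the DSEL with seeded k-means and precomputes, per cluster, each
#' model's accuracy and the pairwise double-fault rates used as the
#' (inverse) diversity measure.
#'
#' @param pool a `model_pool`.
#' @param n_clusters number of k-means clusters (default 5).
#' @param seed integer seed for the clustering.
#' @return a `desc_state` list: `centers`, `assignment`, `accuracy`
#'   (n_models x n_clusters), `double_fault` (list of n_models x n_models
#'   matrices per cluster).
#' @export
desc_state <- function(pool, n_clusters = 5, seed = 1L) {
  dsel_X <- pool$dsel_X
  n_clusters <- min(n_clusters, nrow(dsel_X))
  km <- with_seed(seed, stats::kmeans(dsel_X, centers = n_clusters, nstart = 5))
  corr <- pool_correctness(pool)
  n_models <- nrow(corr)
  accuracy <- matrix(0, n_models, n_clusters)
  double_fault <- vector("list", n_clusters)
  for (cl in seq_len(n_clusters)) {
    cols <- which(km$cluster == cl)
    sub <- corr[, cols, drop = FALSE]
    accuracy[, cl] <- rowMeans(sub)
    wrong <- 1 - sub
    double_fault[[cl]] <- tcrossprod(wrong) / length(cols)
  }
  structure(list(centers = km$centers, assignment = km$cluster,
                 accuracy = accuracy, double_fault = double_fault),
            class = "desc_state")
}

#' DES-Clustering selection
#'
#' For the query's nearest (non-empty) cluster: rank the pool by accuracy on
#' that cluster and keep the top `ceil(frac_accurate * n_models)`; among
#' those, greedily retain the `ceil(frac_diverse * n_models)` most diverse,
#' where pairwise diversity = 1 - double-fault rate (fraction of cluster
#' samples misclassified by both models). The greedy selection starts from the
#' most accurate kept model and repeatedly adds the candidate with the highest
#' mean diversity to the already-selected set (ties: higher accuracy, then
#' lower model index).
#'
#' @param state a [desc_state()].
#' @param query numeric query vector.
#' @param frac_accurate fraction of the pool kept by accuracy (default 0.5).
#' @param frac_diverse fraction of the pool kept after the diversity step
#'   (default 0.33).
#' @return list with `selected`, `weights` (uniform), `cluster`,
#'   `fallback_used` (always `FALSE`; the rule is total).
#' @export
select_desc <- function(state, query, frac_accurate = 0.5, frac_diverse = 0.33) {
  assert_that(frac_accurate > 0 && frac_accurate <= 1, "frac_accurate in (0,1]")
  assert_that(frac_diverse > 0 && frac_diverse <= 1, "frac_diverse in (0,1]")
  non_empty <- which(tabulate(state$assignment, nbins = nrow(state$centers)) > 0)
  d <- sqrt(rowSums(sweep(state$centers[non_empty, , drop = FALSE], 2,
                          as.numeric(query))^2))
  cl <- non_empty[order(d, seq_along(d))[1L]]
  n_models <- nrow(state$accuracy)
  acc <- state$accuracy[, cl]
  n_acc <- min(ceiling(frac_accurate * n_models), n_models)
  kept <- order(-acc, seq_len(n_models))[seq_len(n_acc)]
  n_div <- min(ceiling(frac_diverse * n_models), length(kept))
  df <- state$double_fault[[cl]]
  selected <- kept[1L] # most accurate seeds the greedy diversity step
  candidates <- setdiff(kept, selected)
  while (length(selected) < n_div && length(candidates) > 0) {
    div <- vapply(candidates, function(m) {
      mean(1 - df[m, selected])
    }, numeric(1))
    pick <- candidates[order(-div, -acc[candidates], candidates)[1L]]
    selected <- c(selected, pick)
    candidates <- setdiff(candidates, pick)
  }
  list(selected = sort(selected), weights = rep(1, length(selected)),
       cluster = cl, fallback_used = FALSE)
}

#' Combine the selected models' votes
#'
#' Weighted majority of hard votes (threshold 0.5 on each model's P(D)); vote
#' ties resolve to the label with the higher weighted mean probability, and a
#' residual tie resolves to `"NotD"`. The ensemble score is the weighted mean
#' of the selected models' P(D).
#'
#' @param probs numeric vector: each selected model's P(D) for the query.
#' @param weights positive weights aligned with `probs`.
#' @return list with `label` (`"D"`/`"NotD"`) and `score` in `[0, 1]`.
#' @export
combine_votes <- function(probs, weights = rep(1, length(probs))) {
  assert_that(length(probs) >= 1, "need at least one selected model")
  assert_that(length(weights) == length(probs), "weights/probs mismatch")
  votes_d <- sum(weights[probs > 0.5])
  votes_n <- sum(weights[probs <= 0.5])
  score <- sum(weights * probs) / sum(weights)
  label <- if (votes_d > votes_n) "D"
           else if (votes_d < votes_n) "NotD"
           else if (score > 0.5) "D" else "NotD"
  list(label = factor(label, levels = PHENO_LEVELS), score = score)
}

DES_RULES <- c("desp", "desc", "knorae", "knorau")

#' Dynamic-ensemble predictions for a query set
#'
#' Runs one DES rule over every query row: build the region of competence on
#' the pool's DSEL, select models by the rule, and combine their votes.
#'
#' @param pool a `model_pool`.
#' @param X_query query matrix (same feature space as the pool).
#' @param rule one of `"desp"`, `"desc"`, `"knorae"`, `"knorau"`.
#' @param k region-of-competence size (default 7), ignored by `"desc"`.
#' @param desc_params list of DES-C parameters: `n_clusters`, `frac_accurate`,
#'   `frac_diverse`, `seed`.
#' @return data.frame with one row per query: `label`, `score`,
#'   `fallback_used`, `n_selected`; the per-query selected model indices are in
#'   `attr(, "selected")`.
#' @export
predict_des <- function(pool, X_query, rule = c("desp", "desc", "knorae", "knorau"),
                        k = 7, desc_params = list()) {
  rule <- match.arg(rule)
  X_query <- as.matrix(X_query)
  nq <- nrow(X_query)
  corr <- pool_correctness(pool)
  probs <- t(vapply(pool$models, function(m) predict_proba(m, X_query),
                    numeric(nq)))
  state <- NULL
  if (rule == "desc") {
    state <- desc_state(pool, desc_params$n_clusters %||% 5, desc_params$seed %||% 1L)
  } else {
    k <- min(k, nrow(pool$dsel_X))
  }
  labels <- character(nq)
  scores <- numeric(nq)
  fallback <- logical(nq)
  n_sel <- integer(nq)
  selected_list <- vector("list", nq)
  for (i in seq_len(nq)) {
    if (rule == "desc") {
      sel <- select_desc(state, X_query[i, ],
                         desc_params$frac_accurate %||% 0.5,
                         desc_params$frac_diverse %||% 0.33)
    } else {
      roc <- region_of_competence(X_query[i, ], pool$dsel_X, k)
      corr_sub <- corr[, roc$neighbor_idx, drop = FALSE]
      sel <- switch(rule,
                    desp = select_desp(corr_sub),
                    knorae = select_knorae(corr_sub),
                    knorau = select_knorau(corr_sub))
    }
    dec <- combine_votes(probs[sel$selected, i], sel$weights)
    labels[i] <- as.character(dec$label)
    scores[i] <- dec$score
    fallback[i] <- isTRUE(sel$fallback_used)
    n_sel[i] <- length(sel$selected)
    selected_list[[i]] <- sel$selected
  }
  out <- data.frame(label = factor(labels, levels = PHENO_LEVELS),
                    score = scores, fallback_used = fallback,
                    n_selected = n_sel)
  attr(out, "selected") <- selected_list
  out
}

#' Tune the region-of-competence size k
#'
#' Cross-validates over the DSEL: for each fold, the held-out DSEL rows act as
#' queries while the remaining DSEL rows provide the regions of competence;
#' the rule's out-of-fold AUC is averaged and the k with the highest mean AUC
#' wins (ties: smallest k).
#'
#' @param pool a `model_pool`.
#' @param rule DES rule id.
#' @param k_grid candidate k values (default `c(3, 5, 7, 9, 11)`).
#' @param folds number of DSEL folds (default 5).
#' @param seed integer seed.
#' @return list with `k` (chosen), `mean_auc` per candidate.
#' @export
tune_k <- function(pool, rule, k_grid = c(3, 5, 7, 9, 11), folds = 5, seed = 1L) {
  assert_that(length(k_grid) >= 1, "k_grid must be non-empty")
  if (rule == "desc") return(list(k = k_grid[1L], mean_auc = NA_real_))
  fold_id <- stratified_folds(pool$dsel_y, folds, derive_seed(seed, "tunek"))
  mean_auc <- vapply(k_grid, function(k) {
    fold_auc <- vapply(seq_len(folds), function(f) {
      hold <- fold_id == f
      sub_pool <- new_model_pool(pool$models, pool$families,
                                 pool$dsel_X[!hold, , drop = FALSE],
                                 pool$dsel_y[!hold])
      if (k > sum(!hold)) return(NA_real_)
      pred <- predict_des(sub_pool, pool$dsel_X[hold, , drop = FALSE],
                          rule = rule, k = k)
      if (length(unique(pool$dsel_y[hold])) < 2) return(NA_real_)
      roc_auc(pool$dsel_y[hold], pred$score)$auc
    }, numeric(1))
    mean(fold_auc, na.rm = TRUE)
  }, numeric(1))
  ord <- order(k_grid)
  best_k <- k_grid[ord][which.max(mean_auc[ord])] # first max: smallest k on ties
  list(k = best_k, mean_auc = stats::setNames(mean_auc, k_grid))
}
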