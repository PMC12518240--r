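#' RFE estimator specification
#'
#' The three consensus estimators expose a per-feature importance: random
#' forest (normalised Gini impurity decrease), linear support-vector
#' classifier (absolute primal coefficients) and ridge logistic regression
#' (absolute coefficients; glmnet with a small fixed penalty). A `"fixed"`
#' family (importance given a priori, data-ignored) exists for constructing
#' deterministic test fixtures.
#'
#' @param family `"random_forest"`, `"svm_linear"`, `"logistic"` or `"fixed"`.
#' @param params family hyperparameters; for `"fixed"`, a named numeric
#'   `priority` vector over feature ids (higher = more important).
#' @param seed integer seed.
#' @return an `rfe_estimator`.
#' @export
rfe_estimator <- function(family, params = list(), seed = 1L) {
  family <- match.arg(family, c("random_forest", "svm_linear", "logistic", "fixed"))
  structure(list(family = family, params = params, seed = as.integer(seed)),
            class = "rfe_estimator")
}

# Defaults: the linear estimators are strongly L2-regularised (C = 0.01,
# lambda = 1). With p comparable to n, weakly regularised coefficient
# rankings are dominated by noise directions and the elimination order
# destabilises; strong ridge shrinkage makes the ranking track marginal class
# separation, which is what RFE needs here.
default_rfe_estimators <- function(seed = 1L, rf_ntree = 100) {
  list(
    rfe_estimator("random_forest", list(ntree = rf_ntree), derive_seed(seed, "rf")),
    rfe_estimator("svm_linear", list(C = 0.01), derive_seed(seed, "svm")),
    rfe_estimator("logistic", list(lambda = 1), derive_seed(seed, "lr"))
  )
}

# Fit the estimator and return one non-negative importance per column of X.
fit_importance <- function(est, X, y01) {
  switch(est$family,
    random_forest = {
      mtry <- est$params$mtry %||% max(1L, floor(sqrt(ncol(X))))
      fit <- rf_fit_cpp(X, as.integer(y01),
                        ntree = as.integer(est$params$ntree %||% 100),
                        mtry = as.integer(mtry),
                        min_leaf = as.integer(est$params$min_leaf %||% 1),
                        max_depth = as.integer(est$params$max_depth %||% 0),
                        seed = est$seed)
      as.numeric(fit$importance)
    },
    svm_linear = {
      fit <- fit_svm(list(kernel = "linear", C = est$params$C %||% 1), X, y01)
      abs(fit$w)
    },
    logistic = {
      lam <- est$params$lambda %||% 0.01
      fit <- glmnet::glmnet(X, factor(y01), family = "binomial", alpha = 0,
                            lambda = lam, standardize = FALSE)
      abs(as.numeric(fit$beta))
    },
    fixed = {
      pr <- est$params$priority
      assert_that(!is.null(names(pr)), "fixed estimator needs a named priority vector")
      assert_that(all(colnames(X) %in% names(pr)),
                  "fixed estimator priority does not cover all features")
      as.numeric(pr[colnames(X)])
    }
  )
}

# Removal order for the current importances: least important first; ties are
# broken by removing the lexicographically later feature id first, so the
# lower id survives longer (consistent with the abundance-filter tie-break).
removal_order <- function(imp, ids) order(imp, -xtfrm(ids))

#' Recursive feature elimination to a target size
#'
#' Repeatedly fits the estimator on the surviving features and removes the
#' `step` least-important ones until exactly `target` remain; the last removal
#' is truncated to land on `target`.
#'
#' @param trainer an [rfe_estimator()].
#' @param X numeric matrix (samples x features, named columns), typically CLR.
#' @param y labels.
#' @param target number of features to keep (>= 1).
#' @param step features removed per iteration; `NULL` (default) uses
#'   `max(1, floor(0.05 * n_surviving))`.
#' @return character vector of the `target` surviving feature ids (in original
#'   column order).
#' @export
rfe <- function(trainer, X, y, target, step = NULL) {
  X <- as.matrix(X)
  assert_that(!is.null(colnames(X)), "X needs column names (feature ids)")
  assert_that(target >= 1, "target must be >= 1")
  assert_that(target <= ncol(X),
              sprintf("target %d exceeds %d features", target, ncol(X)))
  y01 <- label01(y)
  surv <- colnames(X)
  while (length(surv) > target) {
    imp <- fit_importance(trainer, X[, surv, drop = FALSE], y01)
    n_remove <- min(step %||% max(1L, floor(0.05 * length(surv))),
                    length(surv) - target)
    drop_idx <- removal_order(imp, surv)[seq_len(n_remove)]
    surv <- surv[-drop_idx]
  }
  colnames(X)[colnames(X) %in% surv]
}

#' Full RFE elimination ranking
#'
#' Runs the elimination schedule down to a single feature, recording the
#' removal order. The returned ranking lists feature ids best-first: the final
#' survivor, then features in reverse removal order (within a removed batch,
#' higher importance at removal time ranks better). The top-t prefix is the
#' nested RFE set of size t.
#'
#' @inheritParams rfe
#' @return character vector of all feature ids, best first.
#' @export
rfe_ranking <- function(trainer, X, y, step = NULL) {
  X <- as.matrix(X)
  assert_that(!is.null(colnames(X)), "X needs column names (feature ids)")
  y01 <- label01(y)
  surv <- colnames(X)
  removed <- character(0)
  while (length(surv) > 1) {
    imp <- fit_importance(trainer, X[, surv, drop = FALSE], y01)
    n_remove <- max(1L, min(step %||% max(1L, floor(0.05 * length(surv))),
                            length(surv) - 1L))
    drop_idx <- removal_order(imp, surv)[seq_len(n_remove)]
    removed <- c(removed, surv[drop_idx])
    surv <- surv[-drop_idx]
  }
  c(surv, rev(removed))
}

#' Consensus recursive feature elimination
#'
#' Runs RFE under the three estimator families at a shared per-estimator
#' target t and searches t = nsf, nsf+1, ..., `t_max` for the first t whose
#' three-way intersection has exactly `nsf` features. By default each
#' estimator's elimination ranking is computed once and the size-t set is its
#' top-t prefix (sets are then nested, so the intersection size is monotone in
#' t and overshooting `nsf` proves the consensus unattainable);
#' `reuse_ranking = FALSE` refits RFE per t instead.
#'
#' @param X training matrix (CLR rows, named columns). Training rows only.
#' @param y training labels.
#' @param nsf desired number of consensus features.
#' @param t_max largest per-estimator target to scan; default
#'   `min(200, ncol(X))`.
#' @param estimators list of three [rfe_estimator()]s; default RF + linear SVC
#'   + ridge logistic.
#' @param step RFE step (see [rfe()]).
#' @param reuse_ranking reuse one elimination ranking per estimator (default
#'   `TRUE`).
#' @param seed integer seed for default estimators.
#' @return a `consensus_selection`: `nsf`, `target_t`, `per_estimator_sets`,
#'   `consensus` (feature ids), `search_trace` (data.frame of t and
#'   intersection size).
#' @export
consensus_select <- function(X, y, nsf, t_max = NULL, estimators = NULL,
                             step = NULL, reuse_ranking = TRUE, seed = 1L) {
  X <- as.matrix(X)
  assert_that(nsf >= 1, "nsf must be >= 1")
  assert_that(nsf <= ncol(X), "nsf exceeds the number of features")
  t_max <- t_max %||% min(200L, ncol(X))
  t_max <- min(t_max, ncol(X))
  estimators <- estimators %||% default_rfe_estimators(seed)
  assert_that(length(estimators) >= 2, "need >= 2 estimators")

  sets_at <- if (reuse_ranking) {
    rankings <- lapply(estimators, function(e) rfe_ranking(e, X, y, step = step))
    function(t) lapply(rankings, function(r) r[seq_len(t)])
  } else {
    function(t) lapply(estimators, function(e) rfe(e, X, y, target = t, step = step))
  }

  trace_t <- integer(0)
  trace_size <- integer(0)
  for (t in seq.int(nsf, t_max)) {
    sets <- sets_at(t)
    inter <- Reduce(intersect, sets)
    trace_t <- c(trace_t, t)
    trace_size <- c(trace_size, length(inter))
    if (length(inter) == nsf) {
      return(structure(list(
        nsf = nsf, target_t = t,
        per_estimator_sets = sets,
        consensus = colnames(X)[colnames(X) %in% inter],
        search_trace = data.frame(t = trace_t, intersection_size = trace_size)),
        class = "consensus_selection"))
    }
    if (reuse_ranking && length(inter) > nsf) break # monotone: can never return
  }
  cond <- structure(
    class = c("phenodes_consensus_error", "phenodes_error", "error", "condition"),
    list(message = sprintf(
      "could not find a consensus of %d features in common for all %d feature selection methods (scanned t = %d..%d)",
      nsf, length(estimators), nsf, trace_t[length(trace_t)]),
      call = sys.call(),
      trace = data.frame(t = trace_t, intersection_size = trace_size)))
  stop(cond)
}

#' @export
print.consensus_selection <- function(x, ...) {
  cat(sprintf("consensus_selection: NSF = %d at target t = %d\n", x$nsf, x$target_t))
  cat("features:", paste(x$consensus, collapse = ", "), "\n")
  invisible(x)
}
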