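#' Base classifier specification
#'
#' @param family one of `"knn"`, `"random_forest"`, `"svm"`, `"xgboost"`,
#'   `"mlp"`.
#' @param grid named list of hyperparameter candidate vectors (list-valued
#'   entries, e.g. hidden-layer shapes, are allowed). `NULL` uses
#'   [default_grids()].
#' @param seed integer seed for any fitting randomness.
#' @return a `classifier_spec`.
#' @export
classifier_spec <- function(family, grid = NULL, seed = 1L) {
  family <- match.arg(family, c("knn", "random_forest", "svm", "xgboost", "mlp"))
  if (is.null(grid)) grid <- default_grids()[[family]]
  assert_that(length(grid) > 0, "grid must be non-empty")
  structure(list(family = family, grid = grid, seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Default hyperparameter grids
#'
#' @param reduced if `TRUE`, return single-configuration grids (fast smoke
#'   settings for tests and small synthetic runs).
#' @return named list of grids, one per family.
#' @export
default_grids <- function(reduced = FALSE) {
  if (reduced) {
    return(list(
      knn = list(n_neighbors = 5, weights = "uniform"),
      random_forest = list(ntree = 100, max_depth = 0, min_leaf = 1),
      svm = list(kernel = "linear", C = 1),
      xgboost = list(nrounds = 100, max_depth = 3, eta = 0.3),
      mlp = list(hidden = list(32), alpha = 1e-4)
    ))
  }
  list(
    knn = list(n_neighbors = c(3, 5, 7, 11), weights = c("uniform", "distance")),
    random_forest = list(ntree = c(200, 500), max_depth = c(0, 10),
                         min_leaf = c(1, 5)),
    svm = list(kernel = c("rbf", "linear"), C = c(0.1, 1, 10)),
    xgboost = list(nrounds = 200, max_depth = c(3, 6), eta = c(0.1, 0.3)),
    mlp = list(hidden = list(c(64), c(128, 64)), alpha = c(1e-4, 1e-3))
  )
}

# ---- fitting ----------------------------------------------------------------

#' Fit a base classifier
#'
#' Uniform fitting front end for the five families. All models expose the same
#' probability contract through [predict_proba()]: a vector of P(D) in
#' `[0, 1]`, with P(NotD) = 1 - P(D).
#'
#' @param family family name (see [classifier_spec()]).
#' @param params named list of hyperparameters for that family.
#' @param X numeric matrix (samples x features), typically CLR-transformed.
#' @param y labels (`"D"`/`"NotD"`).
#' @param seed integer seed.
#' @return a fitted `pheno_model`.
#' @export
fit_classifier <- function(family, params, X, y, seed = 1L) {
  X <- as.matrix(X)
  y01 <- label01(y)
  assert_that(length(unique(y01)) == 2, "need both classes to fit")
  fit <- switch(family,
    knn = fit_knn(params, X, y01),
    random_forest = fit_rf(params, X, y01, seed),
    svm = fit_svm(params, X, y01),
    xgboost = fit_xgb(params, X, y01),
    mlp = fit_mlp(params, X, y01, seed),
    abort_pheno(sprintf("unknown family '%s'", family), "phenodes_validation_error")
  )
  structure(list(family = family, params = params, fit = fit, p = ncol(X)),
            class = "pheno_model")
}

#' Class-probability predictions
#'
#' @param model a fitted `pheno_model`.
#' @param X matrix of query rows (same feature space as training).
#' @return numeric vector of P(D), one per row of `X`.
#' @export
predict_proba <- function(model, X) {
  X <- as.matrix(X)
  assert_that(ncol(X) == model$p, "feature-dimension mismatch at prediction")
  pr <- switch(model$family,
    knn = predict_knn(model$fit, X),
    random_forest = rf_predict_cpp(model$fit$trees, X),
    svm = predict_svm(model$fit, X),
    xgboost = xgb_predict_cpp(model$fit, X),
    mlp = predict_mlp(model$fit, X)
  )
  pmin(pmax(as.numeric(pr), 0), 1)
}

#' Hard label predictions at threshold 0.5
#'
#' @inheritParams predict_proba
#' @return factor of `"D"`/`"NotD"`.
#' @export
predict_label <- function(model, X) {
  factor(ifelse(predict_proba(model, X) > 0.5, "D", "NotD"), levels = PHENO_LEVELS)
}

# kNN: store the training set; neighbours via FNN at prediction time.
fit_knn <- function(params, X, y01) {
  k <- params$n_neighbors %||% 5
  assert_that(k <= nrow(X), "n_neighbors exceeds training size")
  list(X = X, y01 = y01, k = k, weights = params$weights %||% "uniform")
}

predict_knn <- function(fit, X) {
  nn <- FNN::get.knnx(fit$X, X, k = fit$k)
  lab <- matrix(fit$y01[nn$nn.index], nrow = nrow(X))
  if (identical(fit$weights, "distance")) {
    w <- 1 / (nn$nn.dist + 1e-12)
    rowSums(lab * w) / rowSums(w)
  } else {
    rowMeans(lab)
  }
}

fit_rf <- function(params, X, y01, seed) {
  mtry <- params$mtry %||% max(1L, floor(sqrt(ncol(X))))
  rf_fit_cpp(X, as.integer(y01),
             ntree = as.integer(params$ntree %||% 200),
             mtry = as.integer(mtry),
             min_leaf = as.integer(params$min_leaf %||% 1),
             max_depth = as.integer(params$max_depth %||% 0),
             seed = as.integer(seed))
}

# Primal squared-hinge SVC. Linear kernel optimises (w, b) directly; RBF uses
# the representer form f(x) = K(x, X) alpha + b with penalty alpha' K alpha.
fit_svm <- function(params, X, y01) {
  kernel <- params$kernel %||% "linear"
  C <- params$C %||% 1
  ypm <- ifelse(y01 == 1, 1, -1)
  n <- nrow(X)
  if (kernel == "linear") {
    p <- ncol(X)
    obj <- function(th) {
      w <- th[seq_len(p)]; b <- th[p + 1]
      f <- drop(X %*% w) + b
      m <- pmax(0, 1 - ypm * f)
      0.5 * sum(w^2) + C * sum(m^2)
    }
    grad <- function(th) {
      w <- th[seq_len(p)]; b <- th[p + 1]
      f <- drop(X %*% w) + b
      m <- pmax(0, 1 - ypm * f)
      gw <- w - 2 * C * drop(crossprod(X, ypm * m))
      gb <- -2 * C * sum(ypm * m)
      c(gw, gb)
    }
    opt <- stats::optim(rep(0, p + 1), obj, grad, method = "BFGS",
                        control = list(maxit = 300, reltol = 1e-10))
    w <- opt$par[seq_len(p)]; b <- opt$par[p + 1]
    dec <- drop(X %*% w) + b
    fit <- list(kernel = "linear", w = w, b = b)
  } else {
    gamma <- params$gamma %||% (1 / (ncol(X) * max(mean(apply(X, 2, stats::var)), 1e-12)))
    K <- rbf_kernel(X, X, gamma)
    obj <- function(th) {
      a <- th[seq_len(n)]; b <- th[n + 1]
      Ka <- drop(K %*% a)
      m <- pmax(0, 1 - ypm * (Ka + b))
      0.5 * sum(a * Ka) + C * sum(m^2)
    }
    grad <- function(th) {
      a <- th[seq_len(n)]; b <- th[n + 1]
      Ka <- drop(K %*% a)
      m <- pmax(0, 1 - ypm * (Ka + b))
      ga <- Ka - 2 * C * drop(K %*% (ypm * m))
      gb <- -2 * C * sum(ypm * m)
      c(ga, gb)
    }
    opt <- stats::optim(rep(0, n + 1), obj, grad, method = "BFGS",
                        control = list(maxit = 300, reltol = 1e-10))
    a <- opt$par[seq_len(n)]; b <- opt$par[n + 1]
    dec <- drop(K %*% a) + b
    fit <- list(kernel = "rbf", alpha = a, b = b, Xtrain = X, gamma = gamma)
  }
  fit$platt <- fit_platt(dec, y01)
  fit
}

rbf_kernel <- function(A, B, gamma) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

# Platt sigmoid on training decision values; falls back to a fixed-slope
# sigmoid when the logistic fit degenerates (perfect separation).
fit_platt <- function(dec, y01) {
  co <- tryCatch(
    suppressWarnings(stats::coef(stats::glm(y01 ~ dec, family = stats::binomial()))),
    error = function(e) NULL)
  if (is.null(co) || anyNA(co) || co[2] <= 0) co <- c(0, 2 / max(stats::sd(dec), 1e-6))
  co
}

predict_svm <- function(fit, X) {
  dec <- if (fit$kernel == "linear") {
    drop(X %*% fit$w) + fit$b
  } else {
    drop(rbf_kernel(X, fit$Xtrain, fit$gamma) %*% fit$alpha) + fit$b
  }
  stats::plogis(fit$platt[1] + fit$platt[2] * dec)
}

fit_xgb <- function(params, X, y01) {
  xgb_fit_cpp(X, as.integer(y01),
              nrounds = as.integer(params$nrounds %||% 100),
              max_depth = as.integer(params$max_depth %||% 3),
              eta = as.numeric(params$eta %||% 0.3),
              lambda = as.numeric(params$lambda %||% 1),
              min_leaf = as.integer(params$min_leaf %||% 1))
}

# Fully-connected network, ReLU hidden layers, sigmoid output, full-batch Adam
# with early stopping on a stratified 10% validation split.
fit_mlp <- function(params, X, y01, seed) {
  hidden <- params$hidden %||% c(64)
  if (is.list(hidden)) hidden <- unlist(hidden)
  alpha <- params$alpha %||% 1e-4
  lr <- params$lr %||% 0.01
  epochs <- params$epochs %||% 300
  patience <- params$patience %||% 20
  sizes <- c(ncol(X), hidden, 1L)
  with_seed(seed, {
    W <- lapply(seq_len(length(sizes) - 1L), function(l) {
      matrix(stats::rnorm(sizes[l] * sizes[l + 1L], sd = sqrt(2 / sizes[l])),
             sizes[l], sizes[l + 1L])
    })
    b <- lapply(seq_len(length(sizes) - 1L), function(l) rep(0, sizes[l + 1L]))
    # stratified validation carve-out for early stopping
    val <- unlist(lapply(split(seq_along(y01), y01), function(ix) {
      nv <- max(1L, floor(0.1 * length(ix)))
      sample(ix, nv)
    }))
    tr <- setdiff(seq_along(y01), val)
    if (length(unique(y01[val])) < 2 || length(unique(y01[tr])) < 2) {
      tr <- seq_along(y01); val <- seq_along(y01)
    }
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(x) x * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    best <- list(W = W, b = b, loss = Inf, wait = 0L)
    Xtr <- X[tr, , drop = FALSE]; ytr <- y01[tr]
    Xv <- X[val, , drop = FALSE]; yv <- y01[val]
    nL <- length(W)
    for (ep in seq_len(epochs)) {
      a <- list(Xtr)
      for (l in seq_len(nL)) {
        z <- sweep(a[[l]] %*% W[[l]], 2, b[[l]], "+")
        a[[l + 1L]] <- if (l < nL) pmax(z, 0) else stats::plogis(z)
      }
      pr <- a[[nL + 1L]]
      delta <- (pr - ytr) / length(ytr)          # dL/dz at output (BCE+sigmoid)
      for (l in rev(seq_len(nL))) {
        gW <- crossprod(a[[l]], delta) + alpha * W[[l]]
        gb <- colSums(delta)
        if (l > 1L) delta <- (delta %*% t(W[[l]])) * (a[[l]] > 0)
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        cor1 <- 1 - beta1^ep; cor2 <- 1 - beta2^ep
        W[[l]] <- W[[l]] - lr * (mW[[l]] / cor1) / (sqrt(vW[[l]] / cor2) + eps)
        b[[l]] <- b[[l]] - lr * (mb[[l]] / cor1) / (sqrt(vb[[l]] / cor2) + eps)
      }
      pv <- mlp_forward(Xv, W, b)
      vloss <- -mean(yv * log(pv + 1e-12) + (1 - yv) * log(1 - pv + 1e-12))
      if (vloss < best$loss - 1e-6) {
        best <- list(W = W, b = b, loss = vloss, wait = 0L)
      } else {
        best$wait <- best$wait + 1L
        if (best$wait >= patience) break
      }
    }
    list(W = best$W, b = best$b)
  })
}

mlp_forward <- function(X, W, b) {
  a <- X
  nL <- length(W)
  for (l in seq_len(nL)) {
    z <- sweep(a %*% W[[l]], 2, b[[l]], "+")
    a <- if (l < nL) pmax(z, 0) else stats::plogis(z)
  }
  drop(a)
}

predict_mlp <- function(fit, X) mlp_forward(X, fit$W, fit$b)

# ---- cross-validation plumbing ---------------------------------------------

#' Stratified fold assignment
#'
#' @param y labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids in `1..k`.
#' @export
stratified_folds <- function(y, k, seed = 1L) {
  y <- as_pheno_factor(y)
  assert_that(all(table(y) >= k),
              sprintf("a class has fewer than %d samples: stratified %d-fold impossible", k, k),
              class = "phenodes_stratification_error")
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

expand_grid_list <- function(grid) {
  dims <- lapply(grid, function(v) seq_along(v))
  combos <- expand.grid(dims, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(combos)), function(i) {
    stats::setNames(lapply(names(grid), function(nm) {
      v <- grid[[nm]]
      if (is.list(v)) v[[combos[i, nm]]] else v[combos[i, nm]]
    }), names(grid))
  })
}

#' Exhaustive grid search scored by cross-validated AUC
#'
#' Evaluates every grid configuration with stratified k-fold cross-validation,
#' scores each by mean out-of-fold ROC AUC, picks the best (ties broken by
#' grid order) and refits it on all provided rows.
#'
#' @param spec a [classifier_spec()].
#' @param X training matrix.
#' @param y training labels.
#' @param folds number of CV folds (default 10).
#' @param seed integer seed (folds and fits).
#' @return a `tuned_model` list: `family`, `chosen_params`, `cv_auc_mean`,
#'   `model` (refit on all rows), `grid_results` (AUC per configuration).
#' @export
grid_tune <- function(spec, X, y, folds = 10, seed = 1L) {
  assert_that(folds >= 2, "folds must be >= 2")
  X <- as.matrix(X)
  y <- as_pheno_factor(y)
  fold_id <- stratified_folds(y, folds, derive_seed(seed, "folds"))
  configs <- expand_grid_list(spec$grid)
  aucs <- numeric(length(configs))
  for (ci in seq_along(configs)) {
    fold_auc <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      model <- fit_classifier(spec$family, configs[[ci]],
                              X[tr, , drop = FALSE], y[tr],
                              seed = derive_seed(seed, f))
      pr <- predict_proba(model, X[!tr, , drop = FALSE])
      fold_auc[f] <- roc_auc(y[!tr], pr)$auc
    }
    aucs[ci] <- mean(fold_auc)
  }
  best <- which.max(aucs) # ties: first index = grid order
  model <- fit_classifier(spec$family, configs[[best]], X, y,
                          seed = derive_seed(seed, "refit"))
  structure(list(family = spec$family, chosen_params = configs[[best]],
                 cv_auc_mean = aucs[best], model = model,
                 grid_results = aucs),
            class = "tuned_model")
}

#' Assemble the model pool and its dynamic-selection reference set
#'
#' Carves a stratified DSEL (dynamic-selection dataset) out of the training
#' rows, refits every tuned model on the remainder, and packages the result
#' for the DES rules.
#'
#' @param tuned list of `tuned_model`s (>= 2).
#' @param X_train training matrix.
#' @param y_train training labels.
#' @param dsel_fraction fraction of training rows reserved as DSEL, in
#'   (0, 0.5]; default 0.1 (the 10% validation carve-out).
#' @param seed integer seed.
#' @return a `model_pool`: `models` (refit `pheno_model`s), `families`,
#'   `dsel_X`, `dsel_y`, `dsel_idx`, `fit_idx`.
#' @export
build_pool <- function(tuned, X_train, y_train, dsel_fraction = 0.1, seed = 1L) {
  assert_that(length(tuned) >= 2, "dynamic selection needs >= 2 base models")
  assert_that(dsel_fraction > 0 && dsel_fraction <= 0.5,
              "dsel_fraction must be in (0, 0.5]")
  X_train <- as.matrix(X_train)
  y_train <- as_pheno_factor(y_train)
  split <- stratified_split(y_train, 1 - dsel_fraction,
                            derive_seed(seed, "dsel"))
  fit_idx <- split$train_idx
  dsel_idx <- split$test_idx
  assert_that(length(unique(y_train[dsel_idx])) == 2,
              "DSEL lacks a class", class = "phenodes_stratification_error")
  models <- lapply(seq_along(tuned), function(i) {
    fit_classifier(tuned[[i]]$family, tuned[[i]]$chosen_params,
                   X_train[fit_idx, , drop = FALSE], y_train[fit_idx],
                   seed = derive_seed(seed, i))
  })
  new_model_pool(models, vapply(tuned, `[[`, "", "family"),
                 X_train[dsel_idx, , drop = FALSE], y_train[dsel_idx],
                 dsel_idx = dsel_idx, fit_idx = fit_idx)
}

#' Construct a model pool directly from fitted models
#'
#' Lower-level constructor used by [build_pool()] and by the cross-validation
#' driver (where the fold-validation part doubles as DSEL).
#'
#' @param models list of fitted `pheno_model`s.
#' @param families character vector of family names.
#' @param dsel_X,dsel_y the dynamic-selection reference set.
#' @param dsel_idx,fit_idx optional bookkeeping indices.
#' @return a `model_pool`.
#' @export
new_model_pool <- function(models, families, dsel_X, dsel_y,
                           dsel_idx = NULL, fit_idx = NULL) {
  assert_that(length(models) >= 2, "dynamic selection needs >= 2 base models")
  dsel_y <- as_pheno_factor(dsel_y)
  assert_that(length(unique(dsel_y)) == 2, "DSEL lacks a class",
              class = "phenodes_stratification_error")
  structure(list(models = models, families = families,
                 dsel_X = as.matrix(dsel_X), dsel_y = dsel_y,
                 dsel_idx = dsel_idx, fit_idx = fit_idx),
            class = "model_pool")
}
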