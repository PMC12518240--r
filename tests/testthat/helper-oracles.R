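# Independent brute-force oracles, written directly from the verbal rule
# definitions. They deliberately share no code with the package path.

# AUC by exhaustive positive/negative pair counting (0.5 credit for ties).
oracle_auc <- function(labels, scores) {
  y <- as.integer(as.character(labels) == "D" | labels == 1)
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(pos) * length(neg))
}

# k nearest DSEL rows by repeated minimum extraction; ties by lowest index.
oracle_region <- function(query, dsel_X, k) {
  d <- numeric(nrow(dsel_X))
  for (i in seq_len(nrow(dsel_X))) d[i] <- sqrt(sum((dsel_X[i, ] - query)^2))
  picked <- integer(0)
  for (j in seq_len(k)) {
    remaining <- setdiff(seq_along(d), picked)
    best <- remaining[1]
    for (i in remaining) {
      if (d[i] < d[best] - 1e-15) best <- i
    }
    picked <- c(picked, best)
  }
  picked
}

# DES-P: keep models whose region accuracy beats a random classifier (strictly
# greater than 1/n_classes); none -> all models.
oracle_desp <- function(corr, n_classes = 2) {
  acc <- apply(corr, 1, mean)
  sel <- which(acc > 1 / n_classes)
  if (length(sel) == 0) list(selected = seq_len(nrow(corr)), fallback = TRUE)
  else list(selected = sel, fallback = FALSE)
}

# KNORA-E: models perfect on the whole region; shrink the region (drop the
# farthest neighbour) until some model is perfect; empty at k = 1 -> all.
oracle_knorae <- function(corr) {
  for (k in rev(seq_len(ncol(corr)))) {
    sel <- integer(0)
    for (m in seq_len(nrow(corr))) {
      if (all(corr[m, seq_len(k)] == 1)) sel <- c(sel, m)
    }
    if (length(sel) > 0) return(list(selected = sel, fallback = FALSE))
  }
  list(selected = seq_len(nrow(corr)), fallback = TRUE)
}

# KNORA-U: models correct on at least one region sample, weighted by their
# number of correct classifications; none -> all, uniform.
oracle_knorau <- function(corr) {
  counts <- apply(corr, 1, sum)
  sel <- which(counts >= 1)
  if (length(sel) == 0) {
    list(selected = seq_len(nrow(corr)), weights = rep(1, nrow(corr)),
         fallback = TRUE)
  } else {
    list(selected = sel, weights = counts[sel], fallback = FALSE)
  }
}

# DES-Clustering: given the clustering (assignment + centers) and the DSEL
# correctness matrix, re-derive the selection for a query: nearest non-empty
# centroid; keep top ceil(fa * M) by cluster accuracy (ties: lower index);
# then greedily keep ceil(fd * M) by double-fault diversity starting from the
# most accurate (ties: higher accuracy, then lower index).
oracle_desc <- function(query, centers, assignment, corr,
                        frac_accurate = 0.5, frac_diverse = 0.33) {
  M <- nrow(corr)
  sizes <- sapply(seq_len(nrow(centers)), function(cl) sum(assignment == cl))
  cand_cl <- which(sizes > 0)
  dd <- sapply(cand_cl, function(cl) sqrt(sum((centers[cl, ] - query)^2)))
  cl <- cand_cl[which.min(dd)]
  members <- which(assignment == cl)
  acc <- apply(corr[, members, drop = FALSE], 1, mean)
  n_acc <- min(ceiling(frac_accurate * M), M)
  kept <- order(-acc, seq_len(M))[seq_len(n_acc)]
  n_div <- min(ceiling(frac_diverse * M), length(kept))
  dfault <- function(a, b) {
    mean(corr[a, members] == 0 & corr[b, members] == 0)
  }
  sel <- kept[1]
  cand <- setdiff(kept, sel)
  while (length(sel) < n_div && length(cand) > 0) {
    div <- sapply(cand, function(m) mean(sapply(sel, function(s) 1 - dfault(m, s))))
    pick <- cand[order(-div, -acc[cand], cand)[1]]
    sel <- c(sel, pick)
    cand <- setdiff(cand, pick)
  }
  sort(sel)
}

# A pool of "fixed random predictors": each model is a 1-NN memoriser of an
# arbitrary label vector over the DSEL rows, so its DSEL predictions are that
# vector exactly and its correctness pattern is fully controlled.
make_mock_pool <- function(dsel_X, dsel_y, model_labels) {
  models <- lapply(model_labels, function(lab) {
    fit_classifier("knn", list(n_neighbors = 1), dsel_X, lab)
  })
  new_model_pool(models, rep("knn", length(models)), dsel_X, dsel_y)
}

# Small strongly-separated labelled matrix for classifier tests.
make_blobs <- function(n = 60, p = 4, shift = 3, seed = 1) {
  phenodes:::with_seed(seed, {
    y <- rep(c("D", "NotD"), length.out = n)
    X <- matrix(rnorm(n * p), n, p)
    X[y == "D", 1] <- X[y == "D", 1] + shift
    colnames(X) <- paste0("f", seq_len(p))
    list(X = X, y = factor(y, levels = c("NotD", "D")))
  })
}
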