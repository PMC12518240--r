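test_that("region of competence matches the brute-force neighbour oracle", {
  phenodes:::with_seed(1, {
    dsel <- matrix(rnorm(30 * 4), 30, 4)
    for (i in 1:100) {
      q <- rnorm(4)
      k <- sample(1:7, 1)
      roc <- region_of_competence(q, dsel, k)
      expect_identical(roc$neighbor_idx, oracle_region(q, dsel, k))
      expect_true(all(diff(roc$distances) >= 0))
    }
  })
  # query equal to a DSEL row: that row first at distance 0
  roc <- region_of_competence(dsel[17, ], dsel, 3)
  expect_equal(roc$neighbor_idx[1], 17)
  expect_equal(roc$distances[1], 0)
  expect_error(region_of_competence(rnorm(4), dsel, 31), "k must be")
})

test_that("DES-P applies the strict better-than-random rule with fallback", {
  corr <- rbind(c(1, 1, 1, 0, 1, 1, 0, 1, 0, 1), # acc 0.7
                c(1, 0, 1, 0, 1, 0, 1, 0, 1, 0), # acc 0.5 -> excluded
                c(0, 0, 1, 0, 0, 0, 1, 0, 0, 0)) # acc 0.2
  sel <- select_desp(corr)
  expect_equal(sel$selected, 1L)
  expect_false(sel$fallback_used)

  all_perfect <- select_desp(matrix(1, 3, 5))
  expect_equal(all_perfect$selected, 1:3)

  chance <- select_desp(rbind(c(1, 0), c(0, 1))) # both exactly at 0.5
  expect_true(chance$fallback_used)
  expect_equal(chance$selected, 1:2)
})

test_that("KNORA-E shrinks the region until some model is perfect", {
  corr <- rbind(rep(1, 7), c(rep(1, 6), 0), c(rep(0, 7)))
  sel <- select_knorae(corr)
  expect_equal(sel$selected, 1L)
  expect_equal(sel$effective_k, 7L)

  # nobody perfect at k = 3, A and B perfect on the 2 nearest
  corr2 <- rbind(c(1, 1, 0), c(1, 1, 0), c(0, 1, 1))
  sel2 <- select_knorae(corr2)
  expect_equal(sel2$selected, c(1L, 2L))
  expect_equal(sel2$effective_k, 2L)

  none <- select_knorae(matrix(0, 3, 4))
  expect_true(none$fallback_used)
  expect_equal(none$selected, 1:3)
})

test_that("KNORA-U weights by correct counts and excludes never-correct models", {
  corr <- rbind(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0))
  sel <- select_knorau(corr)
  expect_equal(sel$selected, c(1L, 2L))
  expect_equal(unname(sel$weights), c(2, 1))

  full <- select_knorau(matrix(1, 4, 5))
  expect_equal(full$selected, 1:4)
  expect_true(all(full$weights == 5))

  zero <- select_knorau(matrix(0, 2, 3))
  expect_true(zero$fallback_used)
})

test_that("DES-C routes queries to the accurate model of their cluster", {
  # two well-separated clusters; model 1 memorises cluster 1's labels, model 2
  # memorises cluster 2's, the complementary halves are wrong
  phenodes:::with_seed(21, {
    c1 <- matrix(rnorm(20 * 2, mean = 0), 20, 2)
    c2 <- matrix(rnorm(20 * 2, mean = 8), 20, 2)
  })
  dsel_X <- rbind(c1, c2)
  dsel_y <- rep(c("D", "NotD"), 20)
  lab1 <- c(dsel_y[1:20], ifelse(dsel_y[21:40] == "D", "NotD", "D"))
  lab2 <- c(ifelse(dsel_y[1:20] == "D", "NotD", "D"), dsel_y[21:40])
  pool <- make_mock_pool(dsel_X, dsel_y, list(lab1, lab2))
  st <- desc_state(pool, n_clusters = 2, seed = 5)
  s1 <- select_desc(st, c(0, 0), frac_accurate = 0.5, frac_diverse = 0.5)
  s2 <- select_desc(st, c(8, 8), frac_accurate = 0.5, frac_diverse = 0.5)
  expect_equal(s1$selected, 1L)
  expect_equal(s2$selected, 2L)

  st_b <- desc_state(pool, n_clusters = 2, seed = 5)
  expect_identical(st$assignment, st_b$assignment) # seeded clustering
})

test_that("vote combination follows weighted majority with soft tie-breaks", {
  expect_equal(as.character(combine_votes(c(0.9, 0.8, 0.1))$label), "D")
  expect_equal(as.character(combine_votes(c(0.9, 0.1), c(1, 2))$label), "NotD")
  # tie with higher mean probability for D
  tie <- combine_votes(c(0.9, 0.2))
  expect_equal(as.character(tie$label), "D")
  expect_equal(tie$score, 0.55)
  # residual tie (score exactly 0.5) -> NotD
  resid <- combine_votes(c(0.8, 0.2))
  expect_equal(as.character(resid$label), "NotD")
  expect_error(combine_votes(numeric(0)), "at least one")
})

test_that("all four rules match their brute-force oracles on randomized instances", {
  phenodes:::with_seed(31, {
    for (rep in 1:60) {
      M <- sample(2:5, 1)
      nd <- sample(10:30, 1)
      k <- sample(1:7, 1)
      dsel_X <- matrix(rnorm(nd * 3), nd, 3)
      dsel_y <- sample(c("D", "NotD"), nd, replace = TRUE)
      while (length(unique(dsel_y)) < 2) dsel_y <- sample(c("D", "NotD"), nd, TRUE)
      labs <- lapply(seq_len(M), function(m) sample(c("D", "NotD"), nd, TRUE))
      pool <- make_mock_pool(dsel_X, dsel_y, labs)
      corr_full <- pool_correctness(pool)
      q <- rnorm(3)
      idx <- oracle_region(q, dsel_X, k)
      corr <- corr_full[, idx, drop = FALSE]

      expect_equal(select_desp(corr)$selected, oracle_desp(corr)$selected)
      expect_equal(select_knorae(corr)$selected, oracle_knorae(corr)$selected)
      ku <- select_knorau(corr); ko <- oracle_knorau(corr)
      expect_equal(ku$selected, ko$selected)
      expect_equal(unname(ku$weights), unname(ko$weights))

      st <- desc_state(pool, n_clusters = 3, seed = rep)
      expect_equal(select_desc(st, q)$selected,
                   oracle_desc(q, st$centers, st$assignment, corr_full))
    }
  })
})

test_that("a degenerate pool of identical models reproduces the base model", {
  d <- make_blobs(n = 60, p = 4, shift = 2.5, seed = 41)
  m <- fit_classifier("random_forest", list(ntree = 50), d$X, d$y, seed = 3)
  pool <- new_model_pool(list(m, m, m), rep("random_forest", 3),
                         d$X[41:60, ], d$y[41:60])
  qs <- make_blobs(n = 50, p = 4, shift = 2.5, seed = 42)
  base <- predict_label(m, qs$X)
  for (r in c("desp", "desc", "knorae", "knorau")) {
    pred <- predict_des(pool, qs$X, rule = r, k = 7)
    expect_equal(as.character(pred$label), as.character(base), info = r)
  }
})

test_that("a single always-competent model dominates DES-P and KNORA-E", {
  phenodes:::with_seed(51, {
    dsel_X <- matrix(rnorm(20 * 3), 20, 3)
    dsel_y <- rep(c("D", "NotD"), 10)
  })
  good <- dsel_y
  bad1 <- ifelse(dsel_y == "D", "NotD", "D")
  pool <- make_mock_pool(dsel_X, dsel_y, list(bad1, good, bad1))
  qs <- matrix(rnorm(30 * 3), 30, 3)
  good_model <- pool$models[[2]]
  for (r in c("desp", "knorae")) {
    pred <- predict_des(pool, qs, rule = r, k = 5)
    expect_equal(as.character(pred$label),
                 as.character(predict_label(good_model, qs)), info = r)
    expect_true(all(pred$n_selected == 1))
  }
})

test_that("tune_k returns the grid element and is deterministic", {
  d <- make_blobs(n = 120, p = 4, shift = 2, seed = 61)
  tuned <- lapply(c("knn", "svm"), function(fam) {
    grid_tune(classifier_spec(fam, default_grids(TRUE)[[fam]]),
              d$X, d$y, folds = 5, seed = 62)
  })
  pool <- build_pool(tuned, d$X, d$y, dsel_fraction = 0.4, seed = 63)
  single <- tune_k(pool, "desp", k_grid = 5, folds = 3, seed = 64)
  expect_equal(single$k, 5)
  t1 <- tune_k(pool, "desp", k_grid = c(3, 5, 7), folds = 3, seed = 64)
  t2 <- tune_k(pool, "desp", k_grid = c(3, 5, 7), folds = 3, seed = 64)
  expect_identical(t1, t2)
  expect_true(t1$k %in% c(3, 5, 7))
})

test_that("ensemble scores are valid probabilities", {
  d <- make_blobs(n = 80, p = 4, shift = 2, seed = 71)
  tuned <- lapply(c("knn", "random_forest"), function(fam) {
    grid_tune(classifier_spec(fam, default_grids(TRUE)[[fam]]),
              d$X, d$y, folds = 5, seed = 72)
  })
  pool <- build_pool(tuned, d$X, d$y, dsel_fraction = 0.25, seed = 73)
  qs <- make_blobs(n = 40, p = 4, shift = 2, seed = 74)
  for (r in c("desp", "desc", "knorae", "knorau")) {
    pred <- predict_des(pool, qs$X, rule = r)
    expect_true(all(pred$score >= 0 & pred$score <= 1))
    expect_no_error(roc_auc(qs$y, pred$score))
  }
})
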