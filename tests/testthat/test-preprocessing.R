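test_that("sample filter is boundary-inclusive and idempotent", {
  m <- matrix(c(2499, 0, 2500, 0, 7000, 0), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("S", 1:3), c("A", "B")))
  tab <- abundance_table(m)
  out <- filter_samples(tab, 2500)
  expect_equal(rownames(out$counts), c("S2", "S3"))
  expect_equal(attr(out, "n_discarded"), 1)
  again <- filter_samples(out, 2500)
  expect_identical(again$counts, out$counts)
  expect_equal(attr(again, "n_discarded"), 0)

  all_ok <- filter_samples(tab, 10)
  expect_identical(all_ok$counts, tab$counts)
  expect_error(filter_samples(tab, 1e9), "no samples")
})

test_that("a PD-sized fixture with 42 shallow rows loses exactly 42 of 2581 samples", {
  depths <- c(rep(2499, 42), rep(2500, 39), rep(5000, 2500))
  m <- matrix(depths, ncol = 1,
              dimnames = list(sprintf("S%04d", seq_along(depths)), "A"))
  out <- filter_samples(abundance_table(m), 2500)
  expect_equal(attr(out, "n_discarded"), 42)
  expect_equal(phenodes:::n_samples(out), 2581 - 42)
})

test_that("pseudocount closure matches forced arithmetic and closes rows", {
  m <- matrix(c(0, 9, 5, 5), nrow = 2, byrow = TRUE,
              dimnames = list(c("S1", "S2"), c("A", "B")))
  comp <- to_relative(abundance_table(m), 1)
  expect_equal(comp["S1", ], c(A = 1 / 11, B = 10 / 11))
  expect_equal(comp["S2", ], c(A = 0.5, B = 0.5))

  phenodes:::with_seed(3, {
    r <- matrix(rpois(600, 5), 20, 30)
  })
  comp2 <- to_relative(abundance_table(r), 1)
  expect_true(all(abs(rowSums(comp2) - 1) < 1e-12))
  expect_true(all(comp2 > 0))

  zrow <- abundance_table(matrix(c(0, 0, 1, 2), 2, byrow = TRUE))
  expect_error(to_relative(zrow, 0), "pseudocount 0")
})

test_that("top-k keeps the k most abundant features without re-closure, ties to lower id", {
  comp <- matrix(c(0.5, 0.3, 0.2,
                   0.5, 0.3, 0.2), nrow = 2, byrow = TRUE,
                 dimnames = list(NULL, c("F1", "F2", "F3")))
  out <- top_abundant_features(comp, 2)
  expect_equal(colnames(out), c("F1", "F2"))
  expect_equal(out[1, ], c(F1 = 0.5, F2 = 0.3)) # values untouched, rows not re-closed

  ident <- top_abundant_features(comp, 3)
  expect_equal(unname(ident[, ]), unname(comp))

  tie <- phenodes::make_edge_fixtures()$rank_tie # B and C tied at rank 2
  kept <- top_abundant_features(tie, 2)
  expect_equal(colnames(kept), c("A", "B"))

  expect_error(top_abundant_features(comp, 4), "exceeds")
})

test_that("stratified split hits per-class counts exactly and is deterministic", {
  y <- rep(c("D", "NotD"), c(10, 20))
  sp <- stratified_split(y, 0.7, seed = 5)
  expect_equal(sum(y[sp$train_idx] == "D"), 7)
  expect_equal(sum(y[sp$train_idx] == "NotD"), 14)
  expect_identical(sp, stratified_split(y, 0.7, seed = 5))
  expect_error(stratified_split(rep(c("D", "NotD"), c(1, 20)), 0.7, 1),
               "stratify")
})

test_that("splits partition the samples and respect class proportions (property)", {
  phenodes:::with_seed(11, {
    for (i in 1:100) {
      n_d <- sample(3:40, 1); n_n <- sample(3:40, 1)
      y <- sample(rep(c("D", "NotD"), c(n_d, n_n)))
      frac <- runif(1, 0.4, 0.8)
      sp <- stratified_split(y, frac, seed = i)
      expect_length(intersect(sp$train_idx, sp$test_idx), 0)
      expect_setequal(c(sp$train_idx, sp$test_idx), seq_along(y))
      p_train <- mean(y[sp$train_idx] == "D")
      expect_lt(abs(p_train - mean(y == "D")), 1 / min(n_d, n_n))
    }
  })
})

test_that("CLR matches the analytic values, zero-sums rows, and is scale-invariant", {
  expect_equal(clr_transform(matrix(rep(0.25, 4), 1)), matrix(0, 1, 4))

  z <- clr_transform(matrix(c(0.5, 0.25, 0.25), 1))
  expect_equal(as.numeric(z), c(0.4621, -0.2310, -0.2310), tolerance = 1e-3)

  phenodes:::with_seed(4, {
    x <- matrix(rexp(200) + 1e-3, 10, 20)
  })
  z2 <- clr_transform(x)
  expect_true(all(abs(rowSums(z2)) < 1e-9))
  expect_equal(clr_transform(3.7 * x), z2, tolerance = 1e-12)

  # inverse closure recovers the composition
  comp <- x / rowSums(x)
  expect_equal(clr_inverse(clr_transform(comp)), comp, tolerance = 1e-9)

  expect_error(clr_transform(matrix(c(1, 0), 1)), "strictly positive")
})
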