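# Build a CLR-like matrix where the first `n_sig` columns separate the classes
# by `shift` and the rest are standard-normal noise.
make_signal_matrix <- function(n, p, n_sig, shift, seed) {
  phenodes:::with_seed(seed, {
    y <- rep(c("D", "NotD"), length.out = n)
    X <- matrix(rnorm(n * p), n, p)
    for (j in seq_len(n_sig)) X[y == "D", j] <- X[y == "D", j] + shift
    colnames(X) <- sprintf("f%03d", seq_len(p))
    list(X = X, y = y)
  })
}

test_that("RFE keeps a perfectly separating feature against pure noise (5 seeds)", {
  for (seed in 1:5) {
    d <- make_signal_matrix(n = 60, p = 20, n_sig = 1, shift = 8, seed = seed)
    for (fam in c("random_forest", "svm_linear", "logistic")) {
      est <- rfe_estimator(fam, seed = seed)
      kept <- rfe(est, d$X, d$y, target = 1)
      expect_equal(kept, "f001", info = sprintf("%s seed %d", fam, seed))
    }
  }
})

test_that("RFE boundary behaviour: target = p is identity, last step truncates", {
  d <- make_signal_matrix(40, 10, 2, 5, seed = 3)
  est <- rfe_estimator("logistic")
  expect_equal(rfe(est, d$X, d$y, target = 10), colnames(d$X))
  # step larger than the surplus: must land exactly on target
  kept <- rfe(est, d$X, d$y, target = 7, step = 50)
  expect_length(kept, 7)
  expect_error(rfe(est, d$X, d$y, target = 11), "exceeds")
})

test_that("rankings are deterministic and prefix-consistent with rfe()", {
  d <- make_signal_matrix(50, 15, 3, 5, seed = 4)
  est <- rfe_estimator("random_forest", seed = 9)
  r1 <- rfe_ranking(est, d$X, d$y)
  r2 <- rfe_ranking(est, d$X, d$y)
  expect_identical(r1, r2)
  expect_setequal(r1, colnames(d$X))
  expect_true(all(sprintf("f%03d", 1:3) %in% r1[1:6]))
})

test_that("consensus finds planted features when all estimators agree", {
  d <- make_signal_matrix(n = 120, p = 40, n_sig = 10, shift = 6, seed = 5)
  sel <- consensus_select(d$X, d$y, nsf = 10, seed = 5)
  expect_equal(sel$nsf, 10)
  expect_length(sel$consensus, 10)
  expect_gte(sum(sprintf("f%03d", 1:10) %in% sel$consensus), 9)
  expect_true(all(diff(sel$search_trace$t) > 0)) # monotone scan
  expect_equal(length(sel$per_estimator_sets[[1]]), sel$target_t)
  expect_equal(sort(Reduce(intersect, sel$per_estimator_sets)),
               sort(sel$consensus))
})

test_that("nsf = p with t_max = p returns all features", {
  d <- make_signal_matrix(30, 8, 2, 4, seed = 6)
  sel <- consensus_select(d$X, d$y, nsf = 8, t_max = 8, seed = 6)
  expect_setequal(sel$consensus, colnames(d$X))
  expect_equal(sel$target_t, 8)
})

test_that("the adversarial fixture skips NSF = 7 and raises consensus-unattainable", {
  fix <- make_edge_fixtures()$consensus_skip
  err <- expect_error(
    consensus_select(fix$X, fix$y, nsf = fix$nsf_unattainable,
                     estimators = fix$estimators),
    class = "phenodes_consensus_error")
  trace <- err$trace
  expect_true(is.data.frame(trace))
  expect_equal(trace$intersection_size[trace$t == 7], 6)
  expect_equal(trace$intersection_size[trace$t == 8], 8)
  # deterministic: same error again
  expect_error(consensus_select(fix$X, fix$y, nsf = 7, estimators = fix$estimators),
               "consensus of 7")
  # but the neighbouring sizes are attainable
  expect_length(consensus_select(fix$X, fix$y, nsf = 6,
                                 estimators = fix$estimators)$consensus, 6)
  expect_length(consensus_select(fix$X, fix$y, nsf = 8,
                                 estimators = fix$estimators)$consensus, 8)
})

test_that("per-t refitting mode agrees with the ranking mode on a clean fixture", {
  d <- make_signal_matrix(60, 12, 3, 6, seed = 8)
  a <- consensus_select(d$X, d$y, nsf = 3, seed = 8, reuse_ranking = TRUE)
  b <- consensus_select(d$X, d$y, nsf = 3, seed = 8, reuse_ranking = FALSE)
  expect_setequal(a$consensus, b$consensus)
})
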