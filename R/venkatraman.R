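# Rank-based permutation tests for equality of two ROC curves.
#
# Paired design (two markers measured on the same samples): each marker is
# rank-transformed within the sample set; at every rank cutoff c the
# misclassification count e(c) = FP(c) + FN(c) is compared between markers and
# the statistic integrates |e_a(c) - e_b(c)| over cutoffs. The null is
# generated by independently swapping, per sample, the pair of rank scores
# with probability 1/2 and re-ranking.
#
# Unpaired design (two independent samples): both groups are ranked on the
# pooled scale; the statistic integrates the absolute difference in
# (sensitivity + specificity) between the two empirical curves over pooled
# rank cutoffs. The null permutes group membership within each class.

# misclassification-count curve over rank cutoffs 1..n-1, from ranks + labels:
# e(c) = n0 - c + 2 * FN(c), so only FN (cumsum of labels in rank order) is
# needed to compare two markers.
fn_curve <- function(r, y01) {
  cumsum(y01[order(r)])[-length(y01)]
}

paired_stat <- function(ra, rb, y01) {
  n <- length(y01)
  2 * sum(abs(fn_curve(ra, y01) - fn_curve(rb, y01))) / n^2
}

#' Paired Venkatraman test for two ROC curves
#'
#' Compares the ROC curves of two score vectors measured on the same samples
#' with the rank-swap permutation scheme. The statistic is the integrated
#' absolute difference between the empirical curves (zero iff the curves are
#' identical); it is rank-based, hence invariant to monotone transformations
#' of either score. p-value uses the add-one formula
#' `(1 + #permuted >= observed) / (1 + n_permutations)`.
#'
#' @param scores_a,scores_b numeric scores on the same samples.
#' @param labels binary labels (`"D"` positive, or 0/1).
#' @param n_permutations number of permutations (default 999).
#' @param seed integer seed.
#' @return a `roc_comparison`: `statistic`, `n_permutations`, `p_value`,
#'   `mode = "paired"`, `seed`.
#' @export
venkatraman_paired <- function(scores_a, scores_b, labels,
                               n_permutations = 999, seed = 1L) {
  assert_that(n_permutations >= 1, "n_permutations must be >= 1")
  y01 <- if (is.numeric(labels) && all(labels %in% c(0, 1))) as.integer(labels)
         else label01(labels)
  n <- length(y01)
  assert_that(length(scores_a) == n && length(scores_b) == n, "length mismatch")
  assert_that(sum(y01) > 0 && sum(y01) < n, "both classes required",
              class = "phenodes_degenerate_error")
  ra <- rank(scores_a, ties.method = "first")
  rb <- rank(scores_b, ties.method = "first")
  obs <- paired_stat(ra, rb, y01)
  exceed <- 0L
  with_seed(seed, {
    for (b in seq_len(n_permutations)) {
      swap <- stats::runif(n) < 0.5
      pa <- ifelse(swap, rb, ra)
      pb <- ifelse(swap, ra, rb)
      pa <- rank(pa, ties.method = "first")
      pb <- rank(pb, ties.method = "first")
      if (paired_stat(pa, pb, y01) >= obs - 1e-12) exceed <- exceed + 1L
    }
  })
  structure(list(statistic = obs, n_permutations = n_permutations,
                 p_value = (1 + exceed) / (1 + n_permutations),
                 mode = "paired", seed = as.integer(seed)),
            class = "roc_comparison")
}

# sens+spec curve per group evaluated at every pooled score cutoff (predict
# positive if score > cutoff); comparisons only, hence rank-based and safe
# under tied scores.
unpaired_stat <- function(scores, y01, grp, cuts) {
  curves <- lapply(c(1L, 2L), function(g) {
    sp <- sort(scores[grp == g & y01 == 1])
    sn <- sort(scores[grp == g & y01 == 0])
    sens <- 1 - findInterval(cuts, sp) / length(sp)
    spec <- findInterval(cuts, sn) / length(sn)
    sens + spec
  })
  sum(abs(curves[[1L]] - curves[[2L]])) / length(cuts)
}

#' Unpaired Venkatraman test for two ROC curves
#'
#' Compares the ROC curves of two independent samples (e.g. two data
#' partitions or two imbalance strategies). Group membership is permuted
#' within each class; the pooled ranks never change, so the statistic is
#' rank-based and monotone-invariant.
#'
#' @param scores_a,labels_a first sample.
#' @param scores_b,labels_b second sample.
#' @param n_permutations number of permutations (default 999).
#' @param seed integer seed.
#' @return a `roc_comparison` with `mode = "unpaired"`.
#' @export
venkatraman_unpaired <- function(scores_a, labels_a, scores_b, labels_b,
                                 n_permutations = 999, seed = 1L) {
  assert_that(n_permutations >= 1, "n_permutations must be >= 1")
  to01 <- function(l) if (is.numeric(l) && all(l %in% c(0, 1))) as.integer(l) else label01(l)
  ya <- to01(labels_a)
  yb <- to01(labels_b)
  assert_that(sum(ya) > 0 && sum(ya) < length(ya) &&
              sum(yb) > 0 && sum(yb) < length(yb),
              "both classes required in each sample",
              class = "phenodes_degenerate_error")
  scores <- c(scores_a, scores_b)
  y01 <- c(ya, yb)
  grp <- rep(c(1L, 2L), c(length(ya), length(yb)))
  cuts <- sort(scores)
  obs <- unpaired_stat(scores, y01, grp, cuts)
  exceed <- 0L
  with_seed(seed, {
    for (b in seq_len(n_permutations)) {
      pg <- grp
      for (cls in c(0L, 1L)) {
        idx <- which(y01 == cls)
        pg[idx] <- sample(grp[idx])
      }
      if (unpaired_stat(scores, y01, pg, cuts) >= obs - 1e-12) exceed <- exceed + 1L
    }
  })
  structure(list(statistic = obs, n_permutations = n_permutations,
                 p_value = (1 + exceed) / (1 + n_permutations),
                 mode = "unpaired", seed = as.integer(seed)),
            class = "roc_comparison")
}

#' @export
print.roc_comparison <- function(x, ...) {
  cat(sprintf("%s Venkatraman ROC test: statistic = %.5g, p = %.4g (%d permutations)\n",
              x$mode, x$statistic, x$p_value, x$n_permutations))
  invisible(x)
}
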