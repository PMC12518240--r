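#' Synthetic count-table configuration
#'
#' Describes a sparse 16S-like count table with planted class-discriminative
#' taxa: a heavy-tailed (log-normal) base composition shared by both classes,
#' a log-fold shift of `effect` applied to the informative features between
#' classes, multinomial sampling at heterogeneous library sizes, and
#' class-independent structural zeros.
#'
#' @param n_samples number of samples (default 300).
#' @param n_features number of features (default 200).
#' @param n_informative number of planted discriminative features (default 10).
#' @param effect log-fold shift between classes at informative features
#'   (class D gets `exp(+effect/2)`, NotD `exp(-effect/2)` before closure);
#'   `0` = label-free null. Must be >= 0.
#' @param imbalance minority-class ("D") fraction in (0, 0.5] (0.5 = balanced).
#' @param library_size_range integer pair; per-sample totals drawn uniformly
#'   in this range (default `c(5000, 50000)`).
#' @param sparsity fraction of structural zeros imposed feature-wise by
#'   per-sample Bernoulli thinning, independent of class (default 0.3).
#' @param base_sigma log-normal sd of the base composition (default 1.5,
#'   mimicking real rank-abundance curves).
#' @param strata optional named numeric vector of stratum mixing proportions
#'   (e.g. `c(siteA = 0.6, siteB = 0.4)`).
#' @param seed integer seed.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_samples = 300, n_features = 200,
                             n_informative = 10, effect = 2,
                             imbalance = 0.5,
                             library_size_range = c(5000, 50000),
                             sparsity = 0.3, base_sigma = 1.5,
                             strata = NULL, seed = 1L) {
  assert_that(effect >= 0, "effect must be >= 0")
  assert_that(n_informative <= n_features, "n_informative > n_features")
  assert_that(all(library_size_range >= 1), "library sizes must be >= 1")
  assert_that(imbalance > 0 && imbalance <= 0.5 + 1e-12,
              "imbalance (minority fraction) must be in (0, 0.5]")
  assert_that(sparsity >= 0 && sparsity < 1, "sparsity in [0, 1)")
  structure(list(n_samples = n_samples, n_features = n_features,
                 n_informative = n_informative, effect = effect,
                 imbalance = imbalance,
                 library_size_range = as.integer(library_size_range),
                 sparsity = sparsity, base_sigma = base_sigma,
                 strata = strata, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic abundance table
#'
#' Per sample: the class composition (log-normal base, informative features
#' shifted by `exp(+/- effect/2)`, per-sample log-normal noise, closed to the
#' simplex) is thinned by class-independent structural zeros, re-closed, and
#' counts are drawn multinomially at a uniform-random library size. Fully
#' deterministic given `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return an [abundance_table()] with labels (and stratum when configured);
#'   ground-truth informative feature ids in `attr(, "informative_features")`.
#' @export
generate_table <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    n <- config$n_samples
    p <- config$n_features
    feature_ids <- sprintf("ASV%05d", seq_len(p))
    informative <- feature_ids[seq_len(config$n_informative)]
    base <- exp(stats::rnorm(p, 0, config$base_sigma))
    shift <- rep(0, p)
    shift[seq_len(config$n_informative)] <- config$effect / 2
    n_d <- max(1L, round(config$imbalance * n))
    labels <- c(rep("D", n_d), rep("NotD", n - n_d))
    stratum <- if (!is.null(config$strata)) {
      factor(sample(names(config$strata), n, replace = TRUE,
                    prob = config$strata))
    } else NULL
    counts <- matrix(0, n, p, dimnames = list(sprintf("S%04d", seq_len(n)),
                                              feature_ids))
    keep_prob <- 1 - config$sparsity
    for (i in seq_len(n)) {
      sgn <- if (labels[i] == "D") 1 else -1
      lam <- base * exp(sgn * shift + stats::rnorm(p, 0, 0.5))
      zero <- stats::rbinom(p, 1L, keep_prob) == 0
      lam[zero] <- 0
      if (all(lam == 0)) lam[1L] <- 1 # degenerate guard
      lib <- sample(seq.int(config$library_size_range[1],
                            config$library_size_range[2]), 1L)
      counts[i, ] <- stats::rmultinom(1L, lib, lam / sum(lam))
    }
    tab <- abundance_table(counts, labels = labels, stratum = stratum)
    attr(tab, "informative_features") <- informative
    tab
  })
}

#' Preset synthetic configurations
#'
#' `"signal"`: a strongly discriminative cohort (effect 4, 10 informative
#' features) sized like the saliva cohorts (800 samples). `"null"`: the same
#' cohort with effect 0 (label-free). `"pd_like"`: an imbalanced two-site
#' cohort mimicking the plaque subsets (imbalance + stratum). Sizes are scaled
#' to remain desk-runnable; `n_samples`/`n_features` can be overridden.
#'
#' @param preset `"signal"`, `"null"` or `"pd_like"`.
#' @param n_samples,n_features optional size overrides.
#' @param seed integer seed.
#' @return a [synthetic_config()].
#' @export
synthetic_preset <- function(preset = c("signal", "null", "pd_like"),
                             n_samples = NULL, n_features = NULL, seed = 1L) {
  preset <- match.arg(preset)
  switch(preset,
    signal = synthetic_config(n_samples = n_samples %||% 300,
                              n_features = n_features %||% 200,
                              n_informative = 10, effect = 4,
                              imbalance = 0.4, seed = seed),
    null = synthetic_config(n_samples = n_samples %||% 800,
                            n_features = n_features %||% 150,
                            n_informative = 10, effect = 0,
                            imbalance = 0.5, seed = seed),
    pd_like = synthetic_config(n_samples = n_samples %||% 400,
                               n_features = n_features %||% 300,
                               n_informative = 10, effect = 3,
                               imbalance = 0.25,
                               strata = c(siteA = 0.6, siteB = 0.4),
                               seed = seed)
  )
}

#' Adversarial edge-case fixtures
#'
#' Small deterministic tables exercising the documented edge branches:
#' \describe{
#'   \item{boundary}{row totals straddling the 2,500-count filter, one exactly
#'     at 2,500.}
#'   \item{consensus_skip}{a 10-feature dataset plus three fixed-priority
#'     estimators whose nested intersections jump from 6 to 8 as t increments,
#'     so a consensus of 7 is unattainable.}
#'   \item{rank_tie}{a composition with an exact tie at rank k = 2.}
#'   \item{single_class_stratum}{labels/stratum where one stratum contains a
#'     single class (balancing must fail).}
#' }
#'
#' @return named list of fixtures.
#' @export
make_edge_fixtures <- function() {
  boundary <- abundance_table(
    matrix(c(2499, 0, 2500, 0, 7000, 0), nrow = 3, byrow = TRUE,
           dimnames = list(paste0("S", 1:3), c("F1", "F2"))),
    labels = c("D", "NotD", "D"))

  # consensus-skip: estimators A and B share the identity ranking over
  # f01..f10; C ranks f08 seventh and f07 eighth, so prefix intersections go
  # 6 (t = 7) then 8 (t = 8): a 7-feature consensus never exists.
  ids <- sprintf("f%02d", 1:10)
  pr_ab <- stats::setNames(10:1, ids)
  ord_c <- c(1, 2, 3, 4, 5, 6, 8, 7, 9, 10)
  pr_c <- stats::setNames(10:1, ids[ord_c])
  skip_est <- list(rfe_estimator("fixed", list(priority = pr_ab)),
                   rfe_estimator("fixed", list(priority = pr_ab)),
                   rfe_estimator("fixed", list(priority = pr_c)))
  skip_X <- with_seed(42L, matrix(stats::runif(20 * 10), 20, 10,
                                  dimnames = list(NULL, ids)))
  skip_y <- rep(c("D", "NotD"), 10)

  rank_tie <- matrix(c(0.4, 0.3, 0.3,
                       0.4, 0.3, 0.3), nrow = 2, byrow = TRUE,
                     dimnames = list(paste0("S", 1:2), c("A", "B", "C")))

  list(boundary = boundary,
       consensus_skip = list(X = skip_X, y = skip_y, estimators = skip_est,
                             nsf_unattainable = 7L),
       rank_tie = rank_tie,
       single_class_stratum = list(labels = c("D", "D", "NotD", "NotD"),
                                   stratum = c("A", "A", "B", "B")))
}
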