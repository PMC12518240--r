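#' Preprocessing configuration
#'
#' Constants of the data-processing module: per-sample depth filter,
#' pseudocount, abundance cut, train fraction and split seed.
#'
#' @param min_total_counts minimum total counts per sample (inclusive,
#'   "at least"); default 2500.
#' @param pseudocount constant added to every count before closure; default 1.
#' @param top_k_features number of most-abundant features retained; default 1500.
#' @param train_fraction fraction of samples assigned to training; default 0.7.
#' @param seed split seed.
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(min_total_counts = 2500, pseudocount = 1,
                              top_k_features = 1500, train_fraction = 0.7,
                              seed = 1L) {
  assert_that(min_total_counts >= 0, "min_total_counts must be >= 0")
  assert_that(train_fraction > 0 && train_fraction < 1,
              "train_fraction must be in (0,1)")
  assert_that(top_k_features >= 1, "top_k_features must be >= 1")
  structure(list(min_total_counts = min_total_counts,
                 pseudocount = pseudocount,
                 top_k_features = top_k_features,
                 train_fraction = train_fraction,
                 seed = as.integer(seed)),
            class = "preprocess_config")
}

#' Filter out low-depth samples
#'
#' Retains samples whose total count is at least `min_total_counts`
#' (boundary inclusive). Idempotent.
#'
#' @param table an [abundance_table()].
#' @param min_total_counts inclusive threshold (default 2500).
#' @return the filtered [abundance_table()]; the number of discarded samples is
#'   attached as attribute `"n_discarded"` and logged when
#'   `options(phenodes.verbose = TRUE)`.
#' @export
filter_samples <- function(table, min_total_counts = 2500) {
  validate_abundance_table(table)
  totals <- rowSums(table$counts)
  keep <- totals >= min_total_counts
  assert_that(any(keep), "no samples pass the total-count filter",
              class = "phenodes_empty_error")
  log_msg("sample filter: %d of %d samples discarded (< %g total counts)",
          sum(!keep), length(keep), min_total_counts)
  out <- subset_samples(table, which(keep))
  attr(out, "n_discarded") <- sum(!keep)
  out
}

#' Pseudocount and close to relative abundances
#'
#' Adds `pseudocount` to every entry and divides each row by its sum, yielding
#' strictly positive per-sample compositions (rows sum to 1).
#'
#' @param table an [abundance_table()] (or plain count matrix).
#' @param pseudocount non-negative constant, default 1.
#' @return numeric matrix of relative abundances with the table's dimnames;
#'   labels/stratum are carried in attributes `"labels"` / `"stratum"`.
#' @export
to_relative <- function(table, pseudocount = 1) {
  if (inherits(table, "abundance_table")) {
    validate_abundance_table(table)
    cts <- table$counts
    labels <- table$labels
    stratum <- table$stratum
  } else {
    cts <- table
    labels <- NULL
    stratum <- NULL
  }
  assert_that(nrow(cts) > 0 && ncol(cts) > 0, "empty table",
              class = "phenodes_empty_error")
  x <- cts + pseudocount
  rs <- rowSums(x)
  if (pseudocount == 0 && any(rs == 0)) {
    abort_pheno("all-zero row with pseudocount 0: composition undefined",
                "phenodes_degenerate_error")
  }
  comp <- x / rs
  attr(comp, "labels") <- labels
  attr(comp, "stratum") <- stratum
  comp
}

#' Keep the k most abundant features
#'
#' Ranks features by mean relative frequency over all samples and keeps the
#' top `k`. Retained columns keep their values (the composition is NOT
#' re-closed after the cut). Ties at rank k are broken by feature id
#' (lexicographically smaller id kept).
#'
#' @param comp composition matrix from [to_relative()].
#' @param k number of features to keep; must be `<= ncol(comp)`.
#' @return the column-subset matrix; retained feature ids in
#'   `attr(, "retained_features")`.
#' @export
top_abundant_features <- function(comp, k) {
  assert_that(k >= 1, "k must be >= 1")
  assert_that(k <= ncol(comp),
              sprintf("k = %d exceeds the %d available features", k, ncol(comp)))
  mu <- colMeans(comp)
  ord <- order(-mu, colnames(comp), method = "radix")
  keep <- sort(ord[seq_len(k)])
  out <- comp[, keep, drop = FALSE]
  attr(out, "labels") <- attr(comp, "labels")
  attr(out, "stratum") <- attr(comp, "stratum")
  attr(out, "retained_features") <- colnames(comp)[keep]
  out
}

#' Stratified train/test split
#'
#' Splits sample indices so that each class contributes
#' `round(train_fraction * class size)` samples to the training set (per-class
#' floor with largest-remainder correction, so the global train fraction is
#' met and per-class counts are within one sample of proportionality).
#' Deterministic given `seed`.
#'
#' @param labels binary label vector (`"D"`/`"NotD"`).
#' @param train_fraction fraction in (0,1), default 0.7.
#' @param seed integer seed.
#' @return a `split_spec` list with `train_idx`, `test_idx`, `train_fraction`,
#'   `seed`.
#' @export
stratified_split <- function(labels, train_fraction = 0.7, seed = 1L) {
  labels <- as_pheno_factor(labels)
  assert_that(train_fraction > 0 && train_fraction < 1,
              "train_fraction must be in (0,1)")
  counts <- table(labels)
  assert_that(all(counts >= 2),
              "each class needs >= 2 samples to stratify")
  n <- length(labels)
  # per-class floor + largest remainder so totals hit round(f * n)
  exact <- stats::setNames(train_fraction * as.numeric(counts), names(counts))
  base <- floor(exact)
  target_total <- round(train_fraction * n)
  rem <- exact - base
  add <- target_total - sum(base)
  if (add > 0) {
    ord <- order(-rem)
    base[ord[seq_len(min(add, length(base)))]] <-
      base[ord[seq_len(min(add, length(base)))]] + 1
  }
  base <- pmin(pmax(base, 1), as.numeric(counts) - 1) # both sides non-empty
  train_idx <- integer(0)
  with_seed(seed, {
    for (cl in names(counts)) {
      idx <- which(labels == cl)
      take <- base[[cl]]
      train_idx <- c(train_idx, sort(sample(idx, take)))
    }
  })
  train_idx <- sort(train_idx)
  structure(list(train_idx = train_idx,
                 test_idx = setdiff(seq_len(n), train_idx),
                 train_fraction = train_fraction,
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Centred log-ratio transform
#'
#' Maps each strictly positive composition row x to
#' `ln(x / g(x))` where `g(x)` is the row's geometric mean. Rows of the result
#' sum to 0; the map is scale-invariant per row.
#'
#' @param comp strictly positive matrix (rows = samples).
#' @return matrix of the same shape.
#' @export
clr_transform <- function(comp) {
  comp <- as.matrix(comp)
  if (any(comp <= 0)) {
    abort_pheno("CLR requires strictly positive entries; apply to_relative() with a pseudocount first",
                "phenodes_domain_error")
  }
  lx <- log(comp)
  out <- lx - rowMeans(lx)
  dimnames(out) <- dimnames(comp)
  out
}

#' Invert the CLR transform
#'
#' Exponentiates and re-closes each row to sum 1, recovering the composition.
#'
#' @param z CLR matrix.
#' @return composition matrix with rows summing to 1.
#' @export
clr_inverse <- function(z) {
  e <- exp(z)
  e / rowSums(e)
}
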