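#' Construct an abundance table
#'
#' An `abundance_table` holds a samples-by-features matrix of non-negative
#' integer counts (ASVs/OTUs in columns), with optional per-sample binary
#' phenotype labels (`"D"` = diseased / positive class, `"NotD"` = not
#' diseased) and an optional categorical stratum (e.g. collection site).
#'
#' @param counts integer matrix, samples in rows, features in columns. Row and
#'   column names are used as sample and feature ids; generated when absent.
#' @param labels optional character/factor vector in `{"D","NotD"}`, one per
#'   sample.
#' @param stratum optional categorical vector, one per sample.
#' @return an object of class `abundance_table`.
#' @export
abundance_table <- function(counts, labels = NULL, stratum = NULL) {
  assert_that(is.matrix(counts), "counts must be a matrix")
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("S%04d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("ASV%05d", seq_len(ncol(counts)))
  }
  if (!is.null(labels)) {
    assert_that(length(labels) == nrow(counts),
                "labels length must equal number of samples")
    labels <- as_pheno_factor(labels)
  }
  if (!is.null(stratum)) {
    assert_that(length(stratum) == nrow(counts),
                "stratum length must equal number of samples")
    stratum <- factor(stratum)
  }
  x <- structure(list(counts = counts, labels = labels, stratum = stratum),
                 class = "abundance_table")
  validate_abundance_table(x)
}

#' Validate an abundance table
#'
#' Checks the structural invariants: unique sample/feature ids, matching
#' dimensions, and non-negative integral counts.
#'
#' @param x an `abundance_table`.
#' @return `x`, invisibly usable, after validation.
#' @export
validate_abundance_table <- function(x) {
  assert_that(inherits(x, "abundance_table"), "not an abundance_table")
  cts <- x$counts
  assert_that(!anyDuplicated(rownames(cts)), "duplicate sample ids")
  assert_that(!anyDuplicated(colnames(cts)), "duplicate feature ids")
  assert_that(!anyNA(cts), "counts contain NA")
  assert_that(all(cts >= 0), "counts must be non-negative")
  assert_that(all(abs(cts - round(cts)) < 1e-8), "counts must be integral")
  if (!is.null(x$labels)) {
    assert_that(length(x$labels) == nrow(cts), "labels/sample mismatch")
  }
  if (!is.null(x$stratum)) {
    assert_that(length(x$stratum) == nrow(cts), "stratum/sample mismatch")
  }
  x
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d features\n",
              nrow(x$counts), ncol(x$counts)))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat(sprintf("labels: D = %d, NotD = %d\n", tab[["D"]], tab[["NotD"]]))
  }
  if (!is.null(x$stratum)) {
    cat("strata:", paste(levels(x$stratum), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$counts)

n_samples <- function(x) nrow(x$counts)
n_features <- function(x) ncol(x$counts)

sample_ids <- function(x) rownames(x$counts)
feature_ids <- function(x) colnames(x$counts)

# Row subset preserving labels/stratum.
subset_samples <- function(x, idx) {
  abundance_table(x$counts[idx, , drop = FALSE],
                  labels = if (!is.null(x$labels)) x$labels[idx],
                  stratum = if (!is.null(x$stratum)) droplevels(x$stratum[idx]))
}
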