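#' Read a count table from TSV or BIOM
#'
#' TSV layout: tab-separated, no quoting, a header line, and the first column
#' holding ids — sample ids when `orientation = "samples_as_rows"`, feature ids
#' when `orientation = "features_as_rows"` (the common mothur/QIIME export).
#' `.biom` files are read through the biomformat package (JSON or HDF5) and
#' are feature-by-sample by convention, so `orientation` is ignored for BIOM.
#'
#' @param path file path (`.tsv`/`.txt` or `.biom`).
#' @param orientation `"samples_as_rows"` or `"features_as_rows"`. There is no
#'   silent auto-detection: the layout is always explicit.
#' @return an [abundance_table()] in samples-as-rows orientation.
#' @export
read_table <- function(path, orientation = c("samples_as_rows", "features_as_rows")) {
  orientation <- match.arg(orientation)
  assert_that(file.exists(path), sprintf("file not found: %s", path),
              class = "phenodes_io_error")
  if (grepl("\\.biom$", path, ignore.case = TRUE)) {
    return(read_biom_table(path))
  }
  df <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                      check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) abort_pheno(sprintf("parse error in %s: %s", path,
                                            conditionMessage(e)),
                                    "phenodes_parse_error"))
  assert_that(ncol(df) >= 2, sprintf("%s: need an id column plus counts", path),
              class = "phenodes_parse_error")
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad_row <- which(apply(df[, -1L, drop = FALSE], 1L,
                           function(r) anyNA(suppressWarnings(as.numeric(r)))))[1L]
    abort_pheno(sprintf("parse error in %s: non-numeric count on data line %d",
                        path, bad_row), "phenodes_parse_error")
  }
  if (anyNA(m)) {
    bad_row <- which(rowSums(is.na(m)) > 0)[1L]
    abort_pheno(sprintf("parse error in %s: missing value on data line %d",
                        path, bad_row), "phenodes_parse_error")
  }
  rownames(m) <- ids
  if (orientation == "features_as_rows") m <- t(m)
  abundance_table(m)
}

read_biom_table <- function(path) {
  assert_that(requireNamespace("biomformat", quietly = TRUE),
              "reading BIOM requires the biomformat package",
              class = "phenodes_io_error")
  b <- biomformat::read_biom(path)
  m <- as(biomformat::biom_data(b), "matrix") # features x samples
  abundance_table(t(m))
}

#' Attach phenotype labels (and optional stratum) from a metadata table
#'
#' Samples missing from the metadata are dropped with a warning (public
#' cohorts routinely contain unlabelled samples); metadata rows without a
#' matching sample are ignored.
#'
#' @param table an [abundance_table()].
#' @param metadata data.frame with columns `sample_id`, `label`, and optionally
#'   `stratum`.
#' @param label_map named character vector mapping raw label values to
#'   `"D"`/`"NotD"`, e.g. `c(case = "D", control = "NotD")`. Defaults to the
#'   identity map for values already in `{D, NotD}`.
#' @return a labelled [abundance_table()].
#' @export
join_metadata <- function(table, metadata, label_map = NULL) {
  validate_abundance_table(table)
  assert_that(all(c("sample_id", "label") %in% names(metadata)),
              "metadata needs columns sample_id and label")
  metadata <- metadata[!duplicated(metadata$sample_id), , drop = FALSE]
  keep <- sample_ids(table) %in% metadata$sample_id
  n_drop <- sum(!keep)
  assert_that(any(keep), "no samples left after metadata join",
              class = "phenodes_empty_error")
  if (n_drop > 0) {
    warning(sprintf("dropped %d sample(s) absent from metadata", n_drop))
  }
  table <- subset_samples(table, which(keep))
  md <- metadata[match(sample_ids(table), metadata$sample_id), , drop = FALSE]
  raw <- as.character(md$label)
  if (is.null(label_map)) {
    label_map <- stats::setNames(PHENO_LEVELS, PHENO_LEVELS)
  }
  unmapped <- setdiff(unique(raw), names(label_map))
  assert_that(length(unmapped) == 0,
              sprintf("label value(s) not in label_map: %s",
                      paste(unmapped, collapse = ", ")))
  table$labels <- as_pheno_factor(unname(label_map[raw]))
  if ("stratum" %in% names(md)) table$stratum <- factor(md$stratum)
  validate_abundance_table(table)
}

#' Write an abundance table to TSV
#'
#' Writes the counts samples-as-rows (first column `sample_id`). When labels
#' are present a sidecar metadata TSV `<path>.meta.tsv` (columns `sample_id`,
#' `label`, optional `stratum`) is written alongside so that
#' `read_table()` + [join_metadata()] round-trips the object.
#'
#' @param table an [abundance_table()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path) {
  validate_abundance_table(table)
  assert_that(n_features(table) > 0, "nothing to write: table has no features",
              class = "phenodes_empty_error")
  dir_ok <- dir.exists(dirname(path))
  assert_that(dir_ok, sprintf("cannot write to %s", path),
              class = "phenodes_io_error")
  df <- data.frame(sample_id = sample_ids(table),
                   table$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(table$labels)) {
    md <- data.frame(sample_id = sample_ids(table),
                     label = as.character(table$labels),
                     stringsAsFactors = FALSE)
    if (!is.null(table$stratum)) md$stratum <- as.character(table$stratum)
    utils::write.table(md, paste0(path, ".meta.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
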