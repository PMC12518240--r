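test_that("TSV round-trip preserves ids and counts in both orientations", {
  tab <- abundance_table(matrix(c(1, 2, 3, 4, 5, 6), nrow = 3, byrow = TRUE,
                                dimnames = list(paste0("S", 1:3), c("A", "B"))))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_table(tab, tsv)
  back <- read_table(tsv, orientation = "samples_as_rows")
  expect_identical(back$counts, tab$counts)
  expect_equal(nrow(back$counts), 3)

  # transpose by hand -> features_as_rows read gives the identical table
  tsv2 <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(feature_id = colnames(tab$counts), t(tab$counts),
                   check.names = FALSE)
  write.table(df, tsv2, sep = "\t", quote = FALSE, row.names = FALSE)
  back2 <- read_table(tsv2, orientation = "features_as_rows")
  expect_identical(back2$counts, tab$counts)
})

test_that("random tables round-trip bit-for-bit through TSV", {
  phenodes:::with_seed(7, {
    for (i in 1:60) {
      n <- sample(2:10, 1); p <- sample(1:15, 1)
      m <- matrix(rpois(n * p, 20), n, p,
                  dimnames = list(sprintf("S%d", 1:n), sprintf("F%d", 1:p)))
      tab <- abundance_table(m)
      f <- tempfile(fileext = ".tsv")
      write_table(tab, f)
      back <- read_table(f)
      expect_identical(back$counts, tab$counts)
      unlink(f)
    }
  })
})

test_that("random tables round-trip through BIOM", {
  skip_if_not_installed("biomformat")
  phenodes:::with_seed(8, {
    for (i in 1:20) {
      n <- sample(2:8, 1); p <- sample(2:10, 1)
      m <- matrix(rpois(n * p, 10), n, p,
                  dimnames = list(sprintf("S%d", 1:n), sprintf("F%d", 1:p)))
      b <- biomformat::make_biom(t(m)) # biom convention: features x samples
      f <- tempfile(fileext = ".biom")
      suppressWarnings(biomformat::write_biom(b, f))
      back <- read_table(f)
      expect_equal(back$counts[rownames(m), colnames(m)], m)
      unlink(f)
    }
  })
})

test_that("invalid counts are rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tA\tB", "S1\t1\t2", "S2\t-1\t3"), f)
  expect_error(read_table(f), "non-negative")
  writeLines(c("sample_id\tA\tB", "S1\t1\t2", "S2\tx\t3"), f)
  expect_error(read_table(f), "parse error")
  writeLines(c("sample_id\tA\tB", "S1\t1\t2", "S1\t1\t2"), f)
  expect_error(read_table(f), "duplicate")
  expect_error(read_table("/nonexistent/nope.tsv"), "not found")
})

test_that("join_metadata attaches labels, drops unlabelled samples, rejects unmappable values", {
  tab <- abundance_table(matrix(1:6, nrow = 3,
                                dimnames = list(paste0("S", 1:3), c("A", "B"))))
  md <- data.frame(sample_id = paste0("S", 1:3),
                   label = c("case", "control", "case"),
                   stringsAsFactors = FALSE)
  lm <- c(case = "D", control = "NotD")
  out <- join_metadata(tab, md, lm)
  expect_equal(as.character(out$labels), c("D", "NotD", "D"))

  expect_warning(out2 <- join_metadata(tab, md[1:2, ], lm), "dropped 1")
  expect_equal(phenodes:::n_samples(out2), 2)

  md_bad <- transform(md, label = c("case", "maybe", "control"))
  expect_error(join_metadata(tab, md_bad, lm), "maybe")

  expect_error(join_metadata(tab, data.frame(sample_id = "ZZ", label = "case"), lm),
               "no samples")
})

test_that("labelled tables round-trip via the metadata sidecar", {
  phenodes:::with_seed(21, {
    m <- matrix(rpois(50, 30), 10, 5,
                dimnames = list(sprintf("S%d", 1:10), sprintf("F%d", 1:5)))
    tab <- abundance_table(m, labels = rep(c("D", "NotD"), 5),
                           stratum = rep(c("a", "b"), each = 5))
  })
  f <- withr::local_tempfile(fileext = ".tsv")
  write_table(tab, f)
  md <- read.delim(paste0(f, ".meta.tsv"), stringsAsFactors = FALSE)
  back <- join_metadata(read_table(f), md)
  expect_identical(back$counts, tab$counts)
  expect_equal(as.character(back$labels), as.character(tab$labels))
  expect_equal(as.character(back$stratum), as.character(tab$stratum))
})

test_that("writing an empty-feature table errors", {
  tab <- abundance_table(matrix(1:3, nrow = 3,
                                dimnames = list(paste0("S", 1:3), "A")))
  tab$counts <- tab$counts[, 0, drop = FALSE]
  expect_error(write_table(tab, tempfile()), "no features")
})
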