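#' @useDynLib phenodes, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats predict
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible child seed from (seed, tag); stays inside 32-bit range.
derive_seed <- function(seed, tag) {
  tag_num <- if (is.character(tag)) sum(utf8ToInt(tag) * 131^(seq_along(utf8ToInt(tag)) %% 5)) else as.numeric(tag)
  as.integer((as.numeric(seed) * 48271 + tag_num * 16807 + 12345) %% 2147483563) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_pheno <- function(msg, class) {
  stop(structure(class = c(class, "phenodes_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

assert_that <- function(cond, msg, class = "phenodes_validation_error") {
  if (!isTRUE(cond)) abort_pheno(msg, class)
  invisible(TRUE)
}

# Positive-class convention used throughout: labels are a factor with levels
# c("NotD", "D"); "D" (diseased) is the positive class and all scores are P(D).
PHENO_LEVELS <- c("NotD", "D")

as_pheno_factor <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  bad <- setdiff(unique(labels), PHENO_LEVELS)
  assert_that(length(bad) == 0,
              sprintf("labels must be in {D, NotD}; found: %s",
                      paste(bad, collapse = ", ")))
  factor(labels, levels = PHENO_LEVELS)
}

# 0/1 encoding with D = 1; numeric/logical 0-1 vectors pass through.
label01 <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels) && all(labels %in% c(0, 1))) return(as.integer(labels))
  as.integer(as_pheno_factor(labels) == "D")
}

log_msg <- function(..., verbose = getOption("phenodes.verbose", FALSE)) {
  if (isTRUE(verbose)) message(sprintf(...))
  invisible(NULL)
}
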