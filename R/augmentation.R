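#' Plan per-stratum class balancing
#'
#' Computes, per stratum (or globally when `stratum` is `NULL`), how many
#' synthetic minority-class samples are needed to equalise the class counts.
#' Applies to training labels only — test data is never augmented.
#'
#' @param labels training label vector (`"D"`/`"NotD"`).
#' @param stratum optional per-sample categorical vector.
#' @param seed seed recorded in the plan and used by [augment()].
#' @return an `augmentation_plan`: data.frame with columns `class`, `stratum`,
#'   `n_synth`, plus attribute `seed`.
#' @export
plan_balancing <- function(labels, stratum = NULL, seed = 1L) {
  labels <- as_pheno_factor(labels)
  strat <- if (is.null(stratum)) factor(rep("all", length(labels))) else factor(stratum)
  assert_that(length(strat) == length(labels), "stratum/labels length mismatch")
  rows <- list()
  for (s in levels(strat)) {
    in_s <- strat == s
    tab <- table(labels[in_s])
    if (sum(in_s) == 0) next
    if (any(tab == 0)) {
      abort_pheno(sprintf(
        "stratum '%s' has a class with 0 samples: cannot synthesize from nothing", s),
        "phenodes_degenerate_error")
    }
    deficit <- max(tab) - tab
    for (cl in names(deficit)) {
      if (deficit[[cl]] > 0) {
        rows[[length(rows) + 1L]] <-
          data.frame(class = cl, stratum = s, n_synth = as.integer(deficit[[cl]]),
                     stringsAsFactors = FALSE)
      }
    }
  }
  plan <- if (length(rows)) do.call(rbind, rows) else
    data.frame(class = character(0), stratum = character(0),
               n_synth = integer(0), stringsAsFactors = FALSE)
  attr(plan, "seed") <- as.integer(seed)
  attr(plan, "has_stratum") <- !is.null(stratum)
  class(plan) <- c("augmentation_plan", "data.frame")
  plan
}

#' Splice two compositions (compositional CutMix)
#'
#' The child takes x's value where `mask == 1` and y's where `mask == 0`, then
#' is re-closed to sum 1 (single global renormalisation of the spliced
#' vector). With strictly positive parents the child is strictly inside the
#' simplex.
#'
#' @param x,y strictly positive compositions of equal length.
#' @param mask 0/1 vector over features.
#' @return a composition vector summing to 1.
#' @export
cutmix_pair <- function(x, y, mask) {
  assert_that(length(x) == length(y), "parent length mismatch")
  assert_that(length(mask) == length(x), "mask length mismatch")
  raw <- ifelse(mask == 1, x, y)
  raw / sum(raw)
}

#' Execute an augmentation plan
#'
#' For every planned synthetic sample: draw two parents uniformly with
#' replacement from the same (class, stratum) cell, draw an i.i.d.
#' Bernoulli(`p_mask`) feature mask, splice with [cutmix_pair()] and append
#' the child. Original rows are untouched; deterministic given the plan seed.
#'
#' @param comp composition matrix (training rows, rows sum to 1).
#' @param labels training labels aligned with `comp` rows.
#' @param plan an [plan_balancing()] result.
#' @param stratum optional stratum vector aligned with `comp` rows; required
#'   when the plan is stratified.
#' @param p_mask Bernoulli probability of taking a feature from the first
#'   parent; default 0.5.
#' @return list with `comp` (original + synthetic rows), `labels`, `stratum`,
#'   and `synthetic` (logical flag per row).
#' @export
augment <- function(comp, labels, plan, stratum = NULL, p_mask = 0.5) {
  labels <- as_pheno_factor(labels)
  assert_that(nrow(comp) == length(labels), "comp/labels mismatch")
  strat <- if (is.null(stratum)) factor(rep("all", length(labels))) else factor(stratum)
  seed <- attr(plan, "seed") %||% 1L
  new_rows <- list()
  new_labels <- character(0)
  new_strat <- character(0)
  with_seed(seed, {
    for (i in seq_len(nrow(plan))) {
      cl <- plan$class[i]
      s <- plan$stratum[i]
      pool <- which(labels == cl & as.character(strat) == s)
      if (length(pool) == 0) {
        abort_pheno(sprintf("plan demands class %s in stratum %s but no such rows exist",
                            cl, s), "phenodes_degenerate_error")
      }
      for (j in seq_len(plan$n_synth[i])) {
        pa <- pool[sample.int(length(pool), 1L)]
        pb <- pool[sample.int(length(pool), 1L)]
        mask <- stats::rbinom(ncol(comp), 1L, p_mask)
        child <- cutmix_pair(comp[pa, ], comp[pb, ], mask)
        new_rows[[length(new_rows) + 1L]] <- child
        new_labels <- c(new_labels, cl)
        new_strat <- c(new_strat, s)
      }
    }
  })
  if (length(new_rows)) {
    synth <- do.call(rbind, new_rows)
    rownames(synth) <- sprintf("synth%04d", seq_len(nrow(synth)))
    comp_out <- rbind(comp, synth)
    labels_out <- as_pheno_factor(c(as.character(labels), new_labels))
    strat_out <- factor(c(as.character(strat), new_strat))
  } else {
    comp_out <- comp
    labels_out <- labels
    strat_out <- strat
  }
  list(comp = comp_out, labels = labels_out,
       stratum = if (is.null(stratum)) NULL else strat_out,
       synthetic = c(rep(FALSE, length(labels)), rep(TRUE, length(new_labels))))
}

#' Downsample the majority class
#'
#' Comparator strategy for class balancing: per stratum, randomly drops
#' majority-class rows until classes are equal. Deterministic given `seed`.
#'
#' @param labels training labels.
#' @param stratum optional stratum vector.
#' @param seed integer seed.
#' @return integer vector of retained row indices.
#' @export
downsample_majority <- function(labels, stratum = NULL, seed = 1L) {
  labels <- as_pheno_factor(labels)
  strat <- if (is.null(stratum)) factor(rep("all", length(labels))) else factor(stratum)
  keep <- integer(0)
  with_seed(seed, {
    for (s in levels(strat)) {
      idx <- which(strat == s)
      tab <- table(labels[idx])
      m <- min(tab)
      for (cl in names(tab)) {
        cl_idx <- idx[labels[idx] == cl]
        if (length(cl_idx) > m) cl_idx <- sort(sample(cl_idx, m))
        keep <- c(keep, cl_idx)
      }
    }
  })
  sort(keep)
}
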