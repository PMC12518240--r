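#' Pipeline run configuration
#'
#' Bundles the module configurations for an end-to-end run: preprocessing,
#' class-imbalance strategy, consensus feature selection, base-model grids,
#' dynamic ensemble selection and evaluation.
#'
#' @param preprocess a [preprocess_config()].
#' @param nsf_list strictly increasing positive integers: the numbers of
#'   consensus features to evaluate (default `2:15`).
#' @param t_max largest per-estimator RFE target scanned (default
#'   `min(200, n_features)` at run time).
#' @param rfe_step RFE step (`NULL` = 5% rule).
#' @param families base-model families for the pool (default all five).
#' @param grids hyperparameter grids per family; default [default_grids()].
#' @param reduced_grids use single-configuration grids (fast runs).
#' @param tune_folds CV folds for hyperparameter tuning (default 10).
#' @param cv_folds folds for the model-evaluation cross-validation (default
#'   10); `do_cv = FALSE` skips that stage.
#' @param do_cv run the cross-validated evaluation stage (default `TRUE`).
#' @param rules DES rules to build (default all four).
#' @param k region-of-competence size (default 7).
#' @param tune_k_grid if non-`NULL`, tune k over this grid instead of using
#'   `k`.
#' @param dsel_fraction DSEL carve-out fraction at final training (default 0.1).
#' @param imbalance_strategy `"none"`, `"augment"` or `"downsample"`.
#' @param p_mask CutMix mask probability (default 0.5).
#' @param partition_seeds integer vector of split seeds (one per partition;
#'   multi-partition reruns iterate this).
#' @param seed master seed for everything that is not the split.
#' @return a `run_config`.
#' @export
run_config <- function(preprocess = preprocess_config(),
                       nsf_list = 2:15, t_max = NULL, rfe_step = NULL,
                       families = c("knn", "random_forest", "svm", "xgboost", "mlp"),
                       grids = NULL, reduced_grids = FALSE,
                       tune_folds = 10, cv_folds = 10, do_cv = TRUE,
                       rules = DES_RULES, k = 7, tune_k_grid = NULL,
                       dsel_fraction = 0.1,
                       imbalance_strategy = c("none", "augment", "downsample"),
                       p_mask = 0.5, partition_seeds = 1L, seed = 1L) {
  imbalance_strategy <- match.arg(imbalance_strategy)
  assert_that(length(nsf_list) >= 1 && all(nsf_list >= 1) &&
              all(diff(nsf_list) > 0),
              "nsf_list must be strictly increasing positive integers")
  assert_that(length(partition_seeds) >= 1, "need at least one partition seed")
  grids <- grids %||% default_grids(reduced = reduced_grids)
  structure(list(preprocess = preprocess, nsf_list = as.integer(nsf_list),
                 t_max = t_max, rfe_step = rfe_step, families = families,
                 grids = grids, tune_folds = tune_folds, cv_folds = cv_folds,
                 do_cv = do_cv, rules = rules, k = k,
                 tune_k_grid = tune_k_grid, dsel_fraction = dsel_fraction,
                 imbalance_strategy = imbalance_strategy, p_mask = p_mask,
                 partition_seeds = as.integer(partition_seeds),
                 seed = as.integer(seed)),
            class = "run_config")
}

# Balance the training composition according to the configured strategy.
balance_training <- function(comp, y, strat, strategy, seed, p_mask) {
  if (strategy == "augment") {
    plan <- plan_balancing(y, strat, seed = seed)
    aug <- augment(comp, y, plan, stratum = strat, p_mask = p_mask)
    list(comp = aug$comp, y = aug$labels,
         strat = aug$stratum %||% NULL, ids = rownames(aug$comp))
  } else if (strategy == "downsample") {
    keep <- downsample_majority(y, strat, seed = seed)
    list(comp = comp[keep, , drop = FALSE], y = y[keep],
         strat = if (!is.null(strat)) strat[keep] else NULL,
         ids = rownames(comp)[keep])
  } else {
    list(comp = comp, y = y, strat = strat, ids = rownames(comp))
  }
}

#' Run the full classification pipeline
#'
#' Executes, for one partition seed: sample filtering, pseudocount + closure,
#' top-k abundance filtering, stratified 70/30 split, optional class
#' balancing of the training rows, CLR transform, per-NSF consensus feature
#' selection, hyperparameter tuning, cross-validated evaluation, dynamic
#' ensemble construction and test evaluation. NSFs whose consensus is
#' unattainable are logged and skipped.
#'
#' @param config a [run_config()].
#' @param table a labelled [abundance_table()].
#' @param out_dir optional output directory: metrics tables (TSV), consensus
#'   feature lists, AUC-vs-NSF plot and a JSON run manifest are written there.
#' @param partition_seed split seed; default `config$partition_seeds[1]`.
#' @param write_plots write the AUC-vs-NSF plot (default `FALSE`).
#' @return a `pipeline_result`: `metrics` (per model/NSF/split), `averages`
#'   (over NSF), `selections` (per NSF consensus), `skipped_nsf`, `test_scores`
#'   (matrix per model), `test_labels`, `manifest`, `audit` (sample ids seen by
#'   each train-only stage).
#' @export
run_pipeline <- function(config, table, out_dir = NULL,
                         partition_seed = NULL, write_plots = FALSE) {
  stopifnot(inherits(config, "run_config"))
  validate_abundance_table(table)
  assert_that(!is.null(table$labels), "pipeline needs a labelled table")
  partition_seed <- partition_seed %||% config$partition_seeds[1L]

  # ---- module 1: preprocessing ----
  pp <- config$preprocess
  table <- filter_samples(table, pp$min_total_counts)
  comp <- to_relative(table, pp$pseudocount)
  comp <- top_abundant_features(comp, min(pp$top_k_features, ncol(comp)))
  y <- table$labels
  strat <- table$stratum
  split <- stratified_split(y, pp$train_fraction, seed = partition_seed)
  train_ids <- sample_ids(table)[split$train_idx]
  test_ids <- sample_ids(table)[split$test_idx]

  comp_train <- comp[split$train_idx, , drop = FALSE]
  comp_test <- comp[split$test_idx, , drop = FALSE]
  y_train <- y[split$train_idx]
  y_test <- y[split$test_idx]
  strat_train <- if (!is.null(strat)) droplevels(strat[split$train_idx]) else NULL

  bal <- balance_training(comp_train, y_train, strat_train,
                          config$imbalance_strategy,
                          derive_seed(config$seed, "augment"), config$p_mask)
  X_train <- clr_transform(bal$comp)
  X_test <- clr_transform(comp_test)

  audit <- list(augmentation = rownames(comp_train),
                feature_selection = rownames(bal$comp),
                tuning = rownames(bal$comp),
                dsel = character(0),
                test_ids = test_ids)

  # ---- module 2 per NSF ----
  metrics <- list()
  selections <- list()
  skipped <- integer(0)
  test_scores_all <- list()
  model_names <- c(config$families, config$rules)
  for (nsf in config$nsf_list) {
    nsf_seed <- derive_seed(config$seed, nsf)
    sel <- tryCatch(
      consensus_select(X_train, bal$y, nsf = nsf, t_max = config$t_max,
                       step = config$rfe_step, seed = nsf_seed),
      phenodes_consensus_error = function(e) e)
    if (inherits(sel, "phenodes_consensus_error")) {
      log_msg("NSF %d skipped: %s", nsf, conditionMessage(sel))
      skipped <- c(skipped, nsf)
      next
    }
    selections[[as.character(nsf)]] <- sel
    feats <- sel$consensus
    Xtr <- X_train[, feats, drop = FALSE]
    Xte <- X_test[, feats, drop = FALSE]

    tuned <- lapply(config$families, function(fam) {
      grid_tune(classifier_spec(fam, config$grids[[fam]]),
                Xtr, bal$y, folds = config$tune_folds,
                seed = derive_seed(nsf_seed, fam))
    })

    if (isTRUE(config$do_cv)) {
      cvm <- cv_evaluate(comp_train, y_train, tuned, rules = config$rules,
                         folds = config$cv_folds,
                         seed = derive_seed(nsf_seed, "cv"),
                         augment_strategy = config$imbalance_strategy,
                         stratum = strat_train, k = config$k,
                         p_mask = config$p_mask, feature_subset = feats)
      cvm$nsf <- nsf
      metrics[[length(metrics) + 1L]] <- cvm
    }

    pool <- build_pool(tuned, Xtr, bal$y, dsel_fraction = config$dsel_fraction,
                       seed = derive_seed(nsf_seed, "pool"))
    audit$dsel <- union(audit$dsel, bal$ids[pool$dsel_idx])
    k_use <- config$k
    if (!is.null(config$tune_k_grid)) {
      k_use <- tune_k(pool, config$rules[1L], k_grid = config$tune_k_grid,
                      seed = derive_seed(nsf_seed, "k"))$k
    }
    scores <- matrix(NA_real_, length(y_test), length(model_names),
                     dimnames = list(test_ids, model_names))
    for (mi in seq_along(pool$models)) {
      scores[, mi] <- predict_proba(pool$models[[mi]], Xte)
    }
    for (r in config$rules) {
      pred <- predict_des(pool, Xte, rule = r, k = k_use,
                          desc_params = list(seed = derive_seed(nsf_seed, r)))
      scores[, length(config$families) + match(r, config$rules)] <- pred$score
    }
    tm <- metrics_from_scores(y_test, scores, split = "test")
    tm$nsf <- nsf
    metrics[[length(metrics) + 1L]] <- tm
    test_scores_all[[as.character(nsf)]] <- scores
  }
  assert_that(length(metrics) > 0,
              "no NSF in nsf_list yielded a consensus feature set",
              class = "phenodes_consensus_error")
  metrics <- do.call(rbind, metrics)
  averages <- average_over_nsf(metrics)

  manifest <- list(
    package_version = as.character(utils::packageVersion("phenodes")),
    partition_seed = partition_seed,
    master_seed = config$seed,
    imbalance_strategy = config$imbalance_strategy,
    nsf_list = config$nsf_list,
    skipped_nsf = skipped,
    n_samples = list(total = n_samples(table), train = length(train_ids),
                     test = length(test_ids),
                     train_after_balancing = length(bal$y)),
    n_features = list(after_top_k = ncol(comp)),
    families = config$families, rules = config$rules, k = config$k,
    consensus = lapply(selections, function(s)
      list(nsf = s$nsf, target_t = s$target_t, features = s$consensus))
  )

  result <- structure(list(metrics = metrics, averages = averages,
                           selections = selections, skipped_nsf = skipped,
                           test_scores = test_scores_all, test_labels = y_test,
                           manifest = manifest, audit = audit),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_run_outputs(result, out_dir, write_plots)
  result
}

write_run_outputs <- function(result, out_dir, write_plots = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(df) {
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(x) sprintf("%.10g", x))
    df
  }
  utils::write.table(fmt(result$metrics), file.path(out_dir, "metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fmt(result$averages), file.path(out_dir, "metrics_avg.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nsf in names(result$selections)) {
    utils::write.table(
      data.frame(feature = result$selections[[nsf]]$consensus),
      file.path(out_dir, sprintf("features_nsf%s.tsv", nsf)),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (isTRUE(write_plots)) {
    gg <- plot_auc_vs_nsf(result$metrics)
    ggplot2::ggsave(file.path(out_dir, "auc_vs_nsf.png"), gg,
                    width = 8, height = 5, dpi = 120)
  }
  invisible(out_dir)
}

#' Multi-partition comparison
#'
#' Reruns the pipeline once per partition seed and compares the test-set ROC
#' curves of a reference model between partitions with the unpaired
#' Venkatraman test (different partitions have different test samples).
#'
#' @param config a [run_config()] with `>= 2` `partition_seeds`.
#' @param table a labelled [abundance_table()].
#' @param reference_model model column used for the ROC comparisons (default
#'   `"desp"`).
#' @param nsf which NSF's test scores to compare (default: first attained).
#' @param n_permutations permutations for the unpaired test (default 999).
#' @return list with `per_seed` (named list of `pipeline_result`s),
#'   `metrics` (stacked, with a `partition_seed` column) and `comparisons`
#'   (data.frame of pairwise unpaired test results).
#' @export
compare_partitions <- function(config, table, reference_model = "desp",
                               nsf = NULL, n_permutations = 999) {
  seeds <- config$partition_seeds
  assert_that(length(seeds) >= 2, "compare_partitions needs >= 2 partition seeds")
  runs <- lapply(seeds, function(s) run_pipeline(config, table, partition_seed = s))
  names(runs) <- as.character(seeds)
  metrics <- do.call(rbind, lapply(seq_along(seeds), function(i) {
    m <- runs[[i]]$metrics
    m$partition_seed <- seeds[i]
    m
  }))
  comparisons <- list()
  for (i in seq_along(seeds)) {
    for (j in seq_along(seeds)) {
      if (j <= i) next
      nsf_i <- nsf %||% as.integer(names(runs[[i]]$test_scores)[1L])
      si <- runs[[i]]$test_scores[[as.character(nsf_i)]][, reference_model]
      sj <- runs[[j]]$test_scores[[as.character(nsf_i)]][, reference_model]
      vt <- venkatraman_unpaired(si, runs[[i]]$test_labels,
                                 sj, runs[[j]]$test_labels,
                                 n_permutations = n_permutations,
                                 seed = derive_seed(config$seed, i * 1000 + j))
      comparisons[[length(comparisons) + 1L]] <-
        data.frame(seed_a = seeds[i], seed_b = seeds[j], nsf = nsf_i,
                   statistic = vt$statistic, p_value = vt$p_value)
    }
  }
  list(per_seed = runs, metrics = metrics,
       comparisons = do.call(rbind, comparisons))
}

#' Compare class-imbalance strategies
#'
#' Runs the pipeline three times — CutMix augmentation, no balancing, and
#' majority-class downsampling — sharing the same train/test partition, and
#' compares the test ROC curves pairwise with the unpaired Venkatraman test.
#' With balanced input labels only the `"none"` strategy is run (warning).
#'
#' @param config a [run_config()] (its `imbalance_strategy` is overridden).
#' @param table a labelled [abundance_table()].
#' @param reference_model model column compared (default `"desp"`).
#' @param nsf which NSF's test scores to compare (default: first attained).
#' @param n_permutations permutations (default 999).
#' @return list with `per_strategy` results, `metrics` (stacked with a
#'   `strategy` column) and `comparisons`.
#' @export
compare_imbalance_strategies <- function(config, table,
                                         reference_model = "desp", nsf = NULL,
                                         n_permutations = 999) {
  validate_abundance_table(table)
  assert_that(!is.null(table$labels), "needs a labelled table")
  strategies <- c("augment", "none", "downsample")
  if (length(unique(table(table$labels))) == 1L) {
    warning("labels are balanced: only the 'none' strategy is informative")
    strategies <- "none"
  }
  runs <- lapply(strategies, function(s) {
    cfg <- config
    cfg$imbalance_strategy <- s
    run_pipeline(cfg, table, partition_seed = config$partition_seeds[1L])
  })
  names(runs) <- strategies
  metrics <- do.call(rbind, lapply(strategies, function(s) {
    m <- runs[[s]]$metrics
    m$strategy <- s
    m
  }))
  comparisons <- list()
  if (length(strategies) > 1) {
    for (i in seq_along(strategies)) {
      for (j in seq_along(strategies)) {
        if (j <= i) next
        nsf_i <- nsf %||% as.integer(names(runs[[i]]$test_scores)[1L])
        si <- runs[[i]]$test_scores[[as.character(nsf_i)]][, reference_model]
        sj <- runs[[j]]$test_scores[[as.character(nsf_i)]][, reference_model]
        vt <- venkatraman_unpaired(si, runs[[i]]$test_labels,
                                   sj, runs[[j]]$test_labels,
                                   n_permutations = n_permutations,
                                   seed = derive_seed(config$seed, i * 100 + j))
        comparisons[[length(comparisons) + 1L]] <-
          data.frame(strategy_a = strategies[i], strategy_b = strategies[j],
                     nsf = nsf_i, statistic = vt$statistic, p_value = vt$p_value)
      }
    }
  }
  list(per_strategy = runs, metrics = metrics,
       comparisons = if (length(comparisons)) do.call(rbind, comparisons) else NULL)
}
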