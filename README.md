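# phenodes

Binary phenotype classification from 16S rRNA amplicon count tables (ASVs or
OTUs), for microbiome researchers who want a reproducible, leakage-audited
pipeline from a raw count matrix to a tuned dynamic-ensemble classifier — plus
permutation tests for comparing the resulting ROC curves.

## What it does

Given a samples × features table of non-negative integer counts and a binary
phenotype label (`D` = diseased, `NotD` = not diseased), the pipeline runs two
modules:

**Module 1 — data processing**

1. drop samples with fewer than 2,500 total counts;
2. add a pseudocount of 1, close each sample to relative abundances
   (total-sum scaling), and keep the 1,500 most abundant features;
3. stratified 70/30 train/test split;
4. *(optional)* balance the training classes per stratum with **compositional
   CutMix**: a synthetic child of two same-class compositions `x`, `y` and a
   Bernoulli(½) feature mask `m` is
   `child ∝ x^m ∘ y^(1−m)` (take from `x` where `m=1`, from `y` otherwise),
   re-closed to the simplex;
5. centred log-ratio transform per sample, `clr(x)_j = ln(x_j / g(x))` with
   `g(x)` the geometric mean, taking compositions to zero-sum Euclidean
   coordinates;
6. **consensus recursive feature elimination**: RFE under three estimators
   (random forest, linear SVC, ridge logistic regression) at a shared target
   `t`, scanning `t = NSF, NSF+1, …` until the three selections intersect in
   exactly `NSF` features. If the intersection size jumps past `NSF`, that
   consensus is reported unattainable (this genuinely happens).

**Module 2 — training and evaluation**

- five base families — kNN, random forest, SVM (linear/RBF), gradient-boosted
  trees, MLP — grid-tuned by stratified 10-fold cross-validated ROC AUC;
- four **dynamic ensemble selection** rules decide, per query sample, which
  base models vote, based on their correctness in the *region of competence*
  (the `k` nearest samples of a held-out DSEL reference set):
  - **DES-P** — keep models with local accuracy strictly above the ½ chance
    rate;
  - **KNORA-E** — keep models perfect on the whole region, shrinking the
    region until one exists;
  - **KNORA-U** — keep models correct on ≥ 1 neighbour, weighted by their
    number of correct neighbours;
  - **DES-C** — cluster the DSEL (k-means); in the query's cluster keep the
    most accurate half of the pool, then the most diverse third by the
    double-fault measure;
- metrics (F1, precision, recall, accuracy, ROC AUC) per NSF for
  cross-validation and test splits, plus NSF-averaged tables and AUC-vs-NSF
  plots;
- **Venkatraman permutation tests** for equality of two ROC curves: paired
  (two models on the same samples, rank-swap null) and unpaired (two
  partitions or balancing strategies, within-class relabelling null), both
  rank-based with add-one p-values.

A synthetic generator (log-normal base composition, planted log-fold effects,
multinomial sampling at heterogeneous depths, structural zeros, class
imbalance, optional strata) makes the whole pipeline testable with no external
data.

## Worked example

```r
library(phenodes)

tab <- generate_table(synthetic_preset("signal", seed = 1))
tab
#> abundance_table: 300 samples x 200 features
#> labels: D = 120, NotD = 180

cfg <- run_config(preprocess = preprocess_config(seed = 1),
                  nsf_list = c(5L, 10L), reduced_grids = TRUE,
                  tune_folds = 5, cv_folds = 10,
                  imbalance_strategy = "augment", seed = 100)
res <- run_pipeline(cfg, tab)

res$skipped_nsf        # NSF = 5: intersection jumped past 5 -> skipped
#> [1] 5
res$selections[["10"]]
#> consensus_selection: NSF = 10 at target t = 16
#> features: ASV00001, ASV00002, ASV00003, ASV00005, ASV00006, ASV00007,
#>           ASV00008, ASV00009, ASV00010, ASV00091

subset(res$averages, split == "test", select = c(model, roc_auc, f1, accuracy))
#>            model   roc_auc        f1  accuracy
#>             desc 1.0000000 0.9714286 0.9777778
#>             desp 1.0000000 0.9859155 0.9888889
#>              knn 0.9861111 0.9859155 0.9888889
#>           knorae 1.0000000 0.9859155 0.9888889
#>           knorau 1.0000000 0.9859155 0.9888889
#>              mlp 1.0000000 0.9859155 0.9888889
#>    random_forest 1.0000000 1.0000000 1.0000000
#>              svm 1.0000000 0.9714286 0.9777778
#>          xgboost 1.0000000 1.0000000 1.0000000
```

Nine of the ten planted discriminative taxa are recovered at NSF = 10, and on
this strongly separated synthetic cohort the dynamic ensembles and the
stronger base models reach test AUC ≈ 1. `res$metrics` holds the per-NSF
rows; `run_pipeline(..., out_dir = "rundir", write_plots = TRUE)` writes the
metrics TSVs, per-NSF feature lists, a JSON run manifest and the AUC-vs-NSF
plot. `compare_partitions()` and `compare_imbalance_strategies()` rerun the
pipeline across split seeds or balancing strategies and compare the test ROC
curves with the unpaired Venkatraman test.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/phenodes synth --preset signal --out table.tsv --seed 5
Rscript inst/cli/phenodes run --table table.tsv --out rundir \
    --nsf 5,10 --reduced --strategy augment --seed 5
```

## Acceptance script

`scripts/acceptance.R` re-runs the full pipeline from scratch on the
strong-signal synthetic preset (generation → preprocessing → CutMix balancing
→ consensus RFE → tuning → dynamic ensembles → test metrics) and writes the
acceptance JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Scope notes

Upstream read processing (quality control, ASV inference, taxonomy) is out of
scope: the pipeline starts from a count table (TSV or BIOM). Labels are
binary; multi-class phenotypes, static ensembles and dynamic *classifier*
selection (single-model) rules are not implemented. See
`vignettes/phenotype-classification.Rmd` for the methods account and the
design decisions.
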