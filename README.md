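# lupusSSC

Blood-transcriptome subtyping of systemic lupus erythematosus (SLE), for
researchers analyzing longitudinal cohorts where each patient contributes
repeated visits with genome-wide expression and a SLEDAI disease-activity
score. SLE splits along two molecular axes — interferon-stimulated-gene
(IFN) elevation and neutrophil/NET (NE) elevation — into three intrinsic
subtypes (*IFN-high*, *NE-high*, *mixed*) that differ in severity and in
drug benefit. The package implements the full pipeline from raw
expression tables to subtype-stratified treatment statistics, plus a
synthetic cohort generator with planted ground truth that backs
parameter-recovery tests for every stage.

## What it computes

**Disease-activity signature.** Per gene: a one-way ANOVA between SLE and
healthy samples (BH-adjusted), and a patient-weighted activity score

```
score(g) = Σ_p w_p · |r_p(g)|,   w_p ∝ n_visits(p),  Σ w_p = 1,
```

where `r_p(g)` is the Spearman correlation between the gene's expression
and SLEDAI across patient *p*'s visits. The signature is the set of genes
with `q < 0.05` and `score > 0.6`, validated by a row+column permutation
test (add-one estimator) and a random-gene-set comparison.

**Single-sample subtype classifier (SSC).** The number of subtypes is
chosen by majority vote of silhouette, Calinski–Harabasz and gap
criteria; three base clusterings (Euclidean k-medoids, correlation
k-medoids, Ward) are merged through a co-association matrix; centroids in
the standardized signature space are refined by a k-means-style iterative
correction; new samples are assigned one at a time to the nearest
centroid, with `softmax(−distance)` likelihoods. Clusters are named by
their IFN/NE module activity pattern against the healthy baseline.

**Functional profiling.** Gene expression deviation (GED) term activity —
the mean |z| of a term's genes against a healthy reference (leave-one-out
for healthy samples themselves) — plus hypergeometric signature
enrichment, per-subtype module dysregulation profiles, and a term
co-expression network with greedy-modularity communities and
inter-community bridge-node ranking.

**Treatment statistics.** Per-patient SLEDAI change rates (per 30.44-day
month), exposed-vs-unexposed drug-benefit contrasts per subtype,
per-subtype repositioning rates of a targeted drug (interval-level
subtype attribution), and Fisher's exact tests of subtype–demographic
association.

## Worked example

```r
library(lupusSSC)

cfg <- sim_config(n_patients = 30, n_healthy = 15, n_genes = 400, seed = 3)
coh <- generate_cohort(cfg)

scr <- signature_screen(coh$expression, coh$clinical, n_perm = 50, seed = 3)
length(scr$signature)                                # 50
mean(coh$truth$activity_genes %in% scr$signature)    # recall = 1
head(scr$result[, c("gene", "q_value", "score", "perm_p", "selected")], 3)
#>     gene      q_value     score     perm_p selected
#> 1 G00394 3.048011e-06 0.8055989 0.01960784     TRUE
#> 2 G00051 1.563572e-06 0.7950937 0.01960784     TRUE
#> 3 G00367 4.661444e-06 0.7912460 0.01960784     TRUE

sig <- c(coh$truth$ifn_genes, coh$truth$ne_genes)
sle <- coh$clinical$sample_id[coh$clinical$state == "SLE"]
fit <- train_ssc(coh$expression[, sle], sig, seed = 3)
fit$model$k                                          # 3 (all votes agree)
table(fit$labels, coh$truth$subtype_of_sample[names(fit$labels)])
#>     IFN-high mixed NE-high
#>   1       60     0       0
#>   2        0    45       0
#>   3        0     0      67
```

The screen recovers all 50 planted activity genes (`score` is the
weighted |correlation| with SLEDAI, `perm_p` the permutation p at its
add-one floor for 50 permutations), and the consensus clustering
recovers the three planted subtypes exactly. Naming the clusters by
module activity and testing severity:

```r
gs <- build_term_collection(coh$truth, rownames(coh$expression), seed = 3)
act <- ged_activity(coh$expression, coh$clinical, gs)
model <- name_subtypes(fit$model, act, coh$clinical)
asg <- ssc_classify(model, coh$expression[, sle])
sledai_by_subtype(setNames(asg$subtype, asg$sample_id), coh$clinical)$kw_p
#> 2.89e-21   (mixed > IFN-high > NE-high severity ordering)
```

A thin command-line wrapper over the same stage functions is installed at
`inst/scripts/lupus-ssc` with subcommands `simulate`, `preprocess`,
`signature`, `train-ssc`, `classify`, `functional`, `network`,
`treatment`.

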