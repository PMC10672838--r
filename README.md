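# panphen

Classifying **multipartite** (multi-replicon) versus **unipartite**
(single-chromosome) bacterial genomes from gene presence/absence, and
pinpointing the gene families that drive the distinction.

About one bacterium in ten splits its genome across a primary chromosome
plus secondary chromosomes or chromids. Which genes travel with that
architecture? `panphen` answers the question the way a comparative
genomicist would: encode each genome as a binary vector over pan-genome
gene families, benchmark a panel of classifiers on the multipartite /
unipartite label under cross-validation, and keep the gene families that
the classifiers consistently rank as most discriminative. It is aimed at
microbial comparative genomics groups with a labelled genome collection
(annotation tables + protein FASTA, or a ready-made Roary-style matrix) and
at methodologists who want a fully synthetic, ground-truth-bearing testbed
for consensus feature selection on binary matrices.

## What it computes

**Matrix construction.** Named genes are tallied by nomenclature; genes
annotated only as "hypothetical protein" are collapsed into families by
single-linkage clustering over pairwise protein similarity, linking two
genes when a search hit passes E ≤ 10⁻⁵, query coverage ≥ 70% and identity
≥ 30% in at least one direction (internal Smith–Waterman backend, or
BLAST+ if installed). The result is a binary matrix *B* ∈ {0,1}^(n×p)
(genomes × families) with label *y*ᵢ = 1 for multipartite. A
*differential* variant keeps only families that disagree within at least
one (multipartite genome, closest unipartite relative) pair.

**Benchmark.** Twelve classifiers — logR, gNB, SVM, DT, RF, KNN, LDA, mNB,
ABC, GBC, ETC, BC — are evaluated under stratified 6-fold outer
cross-validation with a nested 10-fold accuracy panel inside each training
split. Reported per classifier × feature set × fold: train/test precision,
recall, F1, nested-CV accuracy, AUROC (rank formulation, tie-corrected),
AUPR (step-wise integral), and the Matthews correlation coefficient

    MCC = (TP·TN − FP·FN) / √((TP+FP)(TP+FN)(TN+FP)(TN+FN)),

defined as 0 when a factor vanishes; +1 is perfect, 0 chance, −1 total
disagreement.

**Consensus feature selection.** Per outer fold, features are ranked by
classifier importance (native coefficients/impurity, or permutation
importance). The **Intersection Set** is the features in the top *k*
(default 50) of *every* fold; **Random Sets** are ten matched-size uniform
draws from the All Set, the null reference. The benchmark is re-run on all
three set kinds.

**Segregation & ordination.** Each discriminatory family is assigned to
Set 1 (present in ≥80% of multipartite genomes, ≤20% of unipartite),
Set 2 (the mirror image) or Set 3 (everything else), and genomes are
projected onto the top two principal components of the standard-scaled
Intersection submatrix.

**Synthetic data.** A seeded generator plants Set-1-like and Set-2-like
families (Bernoulli q_high in the enriched class, q_low in the other) among
background families, flips every bit with probability ε, and can emit toy
proteomes with controlled within/between-family identity — so every stage,
including homology clustering, is testable against exact ground truth.

## Worked example

```r
library(panphen)

spec <- synthetic_spec(n_multipartite = 15, n_unipartite = 15,
                       n_background = 200, n_set1 = 10, n_set2 = 10,
                       seed = 42)
gen  <- generate_matrix(spec)
gen$matrix
#> presence_matrix: 30 genomes x 220 gene families
#>   phenotypes: 15 multipartite, 15 unipartite (positive class: multipartite)
#>   density: 0.328
#>   15 multipartite-unipartite pairs

plan <- make_outer_folds(gen$matrix, k = 6, seed = 42)
sets <- build_feature_sets(gen$matrix, plan, top_k = 30, seed = 42)
sets
#> feature_sets: All = 220, Intersection = 21 (top_k = 30, RF/native), 10 random sets

bench <- benchmark_feature_sets(gen$matrix, sets, plan,
                                classifiers = c("logR", "RF", "KNN", "GBC"),
                                seed = 42)
summary(bench)
#>    classifier  feature_set test_f1 nested_cv_accuracy auroc  mcc
#>    GBC         All           0.943              0.931 0.931 0.880
#>    KNN         All           1.000              1.000 1.000 1.000
#>    ...
#>    GBC         Intersection  1.000              1.000 1.000 1.000
#>    ...
#>    logR        Random_mean   0.930              0.931 0.969 0.866
```

All four classifiers hit F1 = 1 on the 21-gene Intersection Set, clearly
above their matched Random Set means (0.88–0.93): the consensus selection
found the planted signal. Segregation then recovers the planted pattern
(10 of the 21 are Set 1, 9 Set 2, 2 ambiguous Set 3):

```r
segregate_sets(gen$matrix, sets$intersection_set)
#> segregation_result: 21 genes -> Set1 10, Set2 9, Set3 2
pca_ordination(gen$matrix, sets$intersection_set)
#> ppa_pca: 30 genomes; PC1 76.4%, PC2 4.3% of variance
```

The whole workflow, including TSV/JSON artifacts and a run manifest, is one
call (`run_pipeline(run_config(spec, seed = 42), "out/")`), or from a
shell via `inst/cli/panphen.R` (subcommands `simulate`, `build-matrix`,
`benchmark`, `select`, `segregate`, `pca`, `run-all`).

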