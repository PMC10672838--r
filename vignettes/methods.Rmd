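---
title: "Methods: presence/absence classification of multipartite and unipartite genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: presence/absence classification of multipartite and unipartite genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(panphen)
```

## The analytical question and the data model

Bacterial genomes come in two architectures: a single chromosome
(unipartite) or a primary chromosome plus one or more secondary
chromosomes/chromids (multipartite). `panphen` treats the architecture as
a binary phenotype and asks which gene families predict it. A genome
collection is reduced to a binary matrix $B \in \{0,1\}^{n \times p}$
(rows genomes, columns gene families, $B_{ij}=1$ iff genome $i$ carries a
member of family $j$) and a label vector $y$, with the multipartite class
coded 1 by default. The coding is configurable because both conventions
appear in practice; every metric here reports the positive class
explicitly, so the choice only relabels output, and flipping it swaps
Set 1 and Set 2 in the segregation step.

Two experiment arms share this representation. The *all-gene* arm uses the
full family set. The *differential* arm first discards every family whose
presence bit agrees between each multipartite genome and its designated
closest unipartite relative in all pairs; what remains are families gained
or lost alongside the architecture change. The pairing is part of the
input (or of the synthetic generator's output); the package does not infer
phylogenetic relatedness.

## Family construction from annotations

Named genes are identified by their nomenclature: one family per distinct
case-insensitive gene name, with no sequence comparison. This follows the
convention that named annotations are already a (curated) orthology
statement; whether named genes should additionally be verified by sequence
similarity is an open judgement call, and we document rather than hide the
choice — name matching only.

Genes annotated merely as "hypothetical protein" carry no usable name, so
they are grouped by sequence: an undirected graph is built over all
hypothetical-protein genes with an edge whenever a similarity hit passes
all of E-value ≤ 10⁻⁵, query coverage ≥ 0.70 and identity ≥ 0.30 in at
least one search direction, and families are the connected components.
Single linkage is the simplest rule consistent with "group genes sharing
high similarity" and is deterministic; requiring reciprocal hits would be
stricter than the thresholds themselves justify, since alignment scores
are asymmetric in coverage. Genes with no passing hit become singleton
families.

Two interchangeable backends produce the hits. The internal backend runs
all-vs-all Smith–Waterman (BLOSUM62, gap open 10 / extend 0.5) via
Biostrings, reporting identity over the aligned region and coverage as
aligned query residues over query length; it estimates no E-value (it
reports 0), so with this backend the E-value gate is vacuous and the
identity/coverage gates do the work. The external backend shells out to
BLAST+ (`makeblastdb`/`blastp`, tabular output) and fills in genuine
E-values; the two backends produce identical partitions on the synthetic
proteomes in the test suite. The internal backend is quadratic in the
number of hypothetical genes and intended for moderate collections; real
pan-genome scale should use BLAST+ or import a Roary matrix directly.

## The cross-validated benchmark

Genomes are split into $k=6$ outer folds, stratified by label; within each
class, genomes are shuffled and dealt round-robin with a rotating offset,
so fold sizes differ by at most one and every fold contains both classes.
Stratification is a deliberate design choice: with ~40 genomes an
unstratified six-way split frequently yields single-class test folds on
which AUROC and AUPR are undefined. Each fold serves once as the test set;
the other five train the model. Inside each training portion only, a
stratified 10-fold cross-validation yields the "nested CV" accuracy panel;
no hyperparameters are tuned there, since all twelve classifiers run at
their libraries' documented defaults, recorded in the run manifest.

The twelve classifiers (logistic regression, Gaussian naive Bayes, RBF
SVM, decision tree, random forest, k-nearest neighbours, linear
discriminant analysis, multinomial naive Bayes, AdaBoost, gradient
boosting, extremely randomized trees, bagging) are wrapped behind one
fit/predict interface with class-1-oriented scores: predicted class-1
probability where available, the decision value for SVM and LDA, the
weighted vote margin for AdaBoost. Per held-out fold we report precision,
recall, F1 (positive class = multipartite), accuracy, the tie-corrected
rank-statistic AUROC, the step-wise precision–recall integral (average
precision) for AUPR, and the Matthews correlation coefficient with the
zero-denominator → 0 convention. Degenerate cases are reported as missing
rather than silently zeroed: AUROC/AUPR on a single-class fold is NA, and
a classifier that fails to fit contributes an all-NA row while the run
continues.

Three wrapper choices deserve a note because naive versions fail on binary
pan-genome matrices, where $p \gg n$ and many columns are constant within
a class:

* **LDA** is a two-class Fisher discriminant on a ridge-regularized pooled
  covariance ($\Sigma + \lambda I$, $\lambda = 10^{-6}\,
  \overline{\mathrm{diag}\,\Sigma} + 10^{-10}$). A pseudoinverse is not
  enough: when the discriminative direction lies in the null space of the
  within-class scatter — exactly the case for a perfectly class-linked
  binary gene — the pseudoinverse projects it away and the classifier
  collapses. The implementation matches classical LDA predictions on
  well-conditioned data (checked against MASS::lda in the tests).
* **Gaussian NB** adds a variance floor of $10^{-9} \times$ the largest
  feature variance so zero-variance features stay usable; **multinomial
  NB** uses add-one smoothing on per-class feature counts.
* **Logistic regression** carries an L2 ridge penalty ($\lambda = 1/n$,
  the $C=1$ convention) because the unpenalized likelihood diverges under
  perfect separation, which planted-signal matrices guarantee.
* **AdaBoost** is 50 rounds of discrete two-class boosting over exact
  depth-1 CART stumps (weighted-Gini split selection, vectorized over the
  binary matrix) with $\alpha_m = \log((1-e_m)/e_m)$; **gradient
  boosting** runs xgboost configured as classic Friedman boosting (100
  rounds, depth 3, learning rate 0.1, no L2 leaf penalty, no
  hessian-based child pruning — the regularized xgboost defaults stop
  adapting on nearly separable data long before 100 rounds); **bagging**
  aggregates 10 bootstrap replicates of an unpruned tree, redrawing the
  rare single-class bootstrap sample.

Every stochastic step draws its seed deterministically from the run seed
and a stage tag, so adding a classifier or feature set does not perturb
the others and identical configurations reproduce outputs bit-identically.

## Consensus selection, the random null, and its caveat

"Importance" is classifier-native where the model has a natural notion
(coefficient magnitudes for the linear models and multinomial NB
log-odds; impurity importances for the tree ensembles) and model-agnostic
permutation importance otherwise (mean training-F1 drop over 10 column
shuffles). Rankings are computed per outer fold on that fold's training
genomes only; ties break by family id for determinism. The Intersection
Set is the features ranked in the top $k$ of all six folds, ordered by
mean rank; $k$ defaults to 50 and is exposed because any specific cutoff
is a judgement call. The default ranking classifier is the random forest
at its full 500 trees — Gini importances over hundreds of
near-equivalent binary features are unstable with small forests, and the
forest size is what carries the consensus property.

Ten Random Sets of the same size are drawn uniformly from the All Set
(intersection members are not excluded — the null is "any set of this
size", not "any disjoint set") and their metrics averaged. Note an
optimistic bias inherited from the protocol being reproduced: the
Intersection Set is re-evaluated on the same outer folds that produced the
rankings, so its features have seen every genome during selection. The
random-set comparison shares the bias direction but not the selection, so
the Intersection–Random gap remains the meaningful contrast; a fully
nested selection inside each training fold is the conservative
alternative when an unbiased absolute estimate is needed.

## Segregation and ordination

For each discriminatory family the per-class presence fractions
$(f_M, f_U)$ are read off the matrix. Set 1 requires
$f_M \ge$ `presence_min` and $f_U \le$ `absence_max`
(defaults 0.8 / 0.2 — our quantification of "present in a large majority,
absent in the relatives"); Set 2 mirrors it; Set 3 is the total
complement, so the three sets always partition the input. Both thresholds
are exposed. Computing fractions on the matrix is exact and
dependency-free; re-deriving presence by sequence search against the
genomes is possible through the homology backend for real-data use where
the matrix itself is in doubt.

The ordination standard-scales the Intersection submatrix column-wise
(population standard deviation, the standard-scaler convention; constant
columns map to zero) and projects genomes on the top two right singular
vectors of the centred matrix. Explained variance comes from the full
singular spectrum. Each component's sign is fixed so its
largest-magnitude loading is positive — PCA is sign-ambiguous, and the
convention makes coordinates and plots reproducible across platforms.

## The synthetic generator: what it does and does not emulate

The generator plants `n_set1` multipartite-enriched and `n_set2`
unipartite-enriched families (Bernoulli `q_high` in the enriched class,
`q_low` in the other) among `n_background` families shared at rate
`p_background`, then flips every bit independently with probability
`epsilon`. Noise-after-planting keeps the ground truth exact, so recovery
rates are directly interpretable. Defaults — 30+30 genomes, 500
background at 0.3, 20+20 planted at 0.95/0.05, ε = 0.02 — mirror the
scale of a ~40-genome comparative study while leaving the signal
recoverable; they are the conditions under which the acceptance properties
are stated. Optional toy proteomes realize the matrix physically: one
random ancestor protein (80–120 aa) per family, rejection-sampled until
inter-family identity sits below `between_family_identity` (default 0.1),
members copied with point substitutions so identity to the ancestor is
exactly `within_family_identity` (default 0.9). Substitution-only
mutation is intentional: identity is then computable by position, making
the generator's contract checkable without alignment.

What the generator does **not** emulate bounds what green tests mean:
columns are independent given the class (no linkage, no phylogenetic
autocorrelation between related genomes), planted effects are
exchangeable, there are no indels, no paralogy, no annotation errors, and
the closest-relative pairing is exact by construction. Passing tests
demonstrate the machinery is correct and the protocol recovers planted
signal under these idealized conditions; they do not certify performance
on real pan-genomes, where phylogenetic structure can make random gene
sets far more (or less) informative than exchangeable nulls suggest.

## Numerical and degenerate-input conventions

Precision is 0 when nothing is predicted positive; MCC is 0 when a
marginal vanishes; AUROC uses midranks for ties; AUPR steps only at
distinct score thresholds, so tied blocks enter together. The proteome
round trip compares matrices on families with at least one carrier — a
family absent from every genome leaves no sequence to recover. Stratified
folding requires at least $k$ genomes per class and says so. Empty
intersections are returned empty with a warning and refused downstream
rather than silently replaced.

## Problem sizes in the shipped checks

The test suite and `scripts/acceptance.R` run the benchmark at the
generator defaults (60 genomes × 540 families) for recovery, ordering and
null controls; homology round trips use 16 genomes × 18 families
(~130 protein sequences), which the quadratic internal aligner handles in
seconds; the determinism check re-runs the orchestrated pipeline twice on
a 24 × 48 matrix with three classifiers. These sizes were chosen as the
smallest at which each property is stable; all scale linearly upward
through the same interfaces.

## Known limitations

The intersection-on-same-folds bias discussed above; name-only matching
of named genes; no E-values from the internal aligner; quadratic internal
alignment; no modelling of phylogenetic non-independence anywhere in the
benchmark (genomes are exchangeable rows); and the differential arm
trusts the user-supplied relative pairing. The eggNOG/COG functional
annotation stage of the typical downstream interpretation is out of
scope: the segregation report only joins a user-supplied
(family, category) table if one is given.
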