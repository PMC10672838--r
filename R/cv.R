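#' Stratified outer cross-validation plan
#'
#' Assigns genomes to `k` (default 6) outer folds, stratified by phenotype:
#' within each class, genomes are shuffled and dealt round-robin, the second
#' class starting where the first class's remainder left off so overall fold
#' sizes differ by at most one. Stratification guarantees every fold holds
#' genomes of both classes, keeping AUROC/AUPR defined on every held-out
#' part.
#'
#' @param pm a [presence_matrix()] (or any object with `labels` and genome
#'   ids as produced by [presence_matrix()]).
#' @param k number of outer folds (default 6).
#' @param seed integer seed; the plan is deterministic under it.
#' @param inner_folds inner fold count used downstream for the nested CV
#'   accuracy panel (default 10).
#' @return object of class `cv_plan`: `fold` (named integer vector, values
#'   in 1..k), `k`, `inner_folds`, `seed`.
#' @export
make_outer_folds <- function(pm, k = 6, seed = 1L, inner_folds = 10L) {
  stopifnot(inherits(pm, "presence_matrix"))
  ids <- genome_ids(pm)
  labs <- pm$labels
  counts <- table(labs)
  if (length(counts) < 2 || any(counts < k))
    stopf("need at least k = %d genomes of each class for stratified %d-fold CV; have %s. Use a smaller k.",
          k, k, paste(counts, collapse = " + "))
  set.seed(derive_seed(seed, "outer-folds", k))
  fold <- integer(length(ids)); names(fold) <- ids
  offset <- 0L
  for (cl in sort(unique(labs), decreasing = TRUE)) {
    members <- sample(ids[labs == cl])
    fold[members] <- ((offset + seq_along(members) - 1L) %% k) + 1L
    offset <- (offset + length(members)) %% k
  }
  plan <- structure(list(fold = fold, k = as.integer(k),
                         inner_folds = as.integer(inner_folds),
                         seed = as.integer(seed)),
                    class = "cv_plan")
  sizes <- tabulate(fold, k)
  stopifnot(max(sizes) - min(sizes) <= 1L)
  plan
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("cv_plan: %d outer folds over %d genomes (inner folds: %d, seed %d)\n",
              x$k, length(x$fold), x$inner_folds, x$seed))
  print(tabulate(x$fold, x$k))
  invisible(x)
}

# Stratified inner folds over a label vector; returns integer assignments.
inner_fold_assign <- function(labs, k, seed) {
  set.seed(seed)
  fold <- integer(length(labs))
  offset <- 0L
  for (cl in sort(unique(labs), decreasing = TRUE)) {
    idx <- sample(which(labs == cl))
    fold[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
    offset <- (offset + length(idx)) %% k
  }
  fold
}
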