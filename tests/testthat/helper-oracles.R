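# Independent brute-force oracles for the classification metrics, kept
# deliberately naive (loops and explicit counting) so they share no code
# path with the package implementation.

oracle_confusion <- function(y_true, y_pred) {
  tp <- tn <- fp <- fn <- 0
  for (i in seq_along(y_true)) {
    if (y_true[i] == 1 && y_pred[i] == 1) tp <- tp + 1
    if (y_true[i] == 0 && y_pred[i] == 0) tn <- tn + 1
    if (y_true[i] == 0 && y_pred[i] == 1) fp <- fp + 1
    if (y_true[i] == 1 && y_pred[i] == 0) fn <- fn + 1
  }
  c(tp = tp, tn = tn, fp = fp, fn = fn)
}

oracle_precision <- function(y_true, y_pred) {
  cc <- oracle_confusion(y_true, y_pred)
  if (cc["tp"] + cc["fp"] == 0) 0 else unname(cc["tp"] / (cc["tp"] + cc["fp"]))
}

oracle_recall <- function(y_true, y_pred) {
  cc <- oracle_confusion(y_true, y_pred)
  if (cc["tp"] + cc["fn"] == 0) 0 else unname(cc["tp"] / (cc["tp"] + cc["fn"]))
}

oracle_f1 <- function(y_true, y_pred) {
  p <- oracle_precision(y_true, y_pred)
  r <- oracle_recall(y_true, y_pred)
  if (p + r == 0) 0 else 2 * p * r / (p + r)
}

oracle_mcc <- function(y_true, y_pred) {
  cc <- as.numeric(oracle_confusion(y_true, y_pred))
  tp <- cc[1]; tn <- cc[2]; fp <- cc[3]; fn <- cc[4]
  d <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (d == 0) 0 else (tp * tn - fp * fn) / sqrt(d)
}

# AUROC as the probability a random positive outscores a random negative,
# by explicit pair enumeration.
oracle_auroc <- function(y_true, y_score) {
  pos <- y_score[y_true == 1]; neg <- y_score[y_true == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# Average precision for tie-free scores: mean over descending-score
# positions k of precision@k restricted to positive positions.
oracle_aupr_unique <- function(y_true, y_score) {
  stopifnot(!anyDuplicated(y_score))
  n_pos <- sum(y_true == 1)
  if (n_pos == 0 || n_pos == length(y_true)) return(NA_real_)
  ord <- order(y_score, decreasing = TRUE)
  yt <- y_true[ord]
  total <- 0
  for (k in seq_along(yt))
    if (yt[k] == 1) total <- total + sum(yt[1:k]) / k
  total / n_pos
}

adjusted_rand_index <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE))
    return(mclust::adjustedRandIndex(a, b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab))); sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n2
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}

# Small specs shared across tests (kept small to bound runtimes).
tiny_spec <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_multipartite = 12, n_unipartite = 12, n_background = 60,
         n_set1 = 5, n_set2 = 5, seed = seed), list(...))
  do.call(synthetic_spec, args)
}

tiny_proteome_spec <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_multipartite = 6, n_unipartite = 6, n_background = 8,
         n_set1 = 3, n_set2 = 3, epsilon = 0, seed = seed,
         emit_proteomes = TRUE), list(...))
  do.call(synthetic_spec, args)
}

# Map recovered family partitions to comparable label vectors: synthetic
# gene ids are "<genome>_<family>", so the generating family is recoverable
# from the gene id.
true_family_of <- function(gene_id) sub("^[MU][0-9]+_", "", gene_id)
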