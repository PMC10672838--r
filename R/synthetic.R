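#' Specification for a synthetic two-class presence/absence dataset
#'
#' Describes a planted-signal binary matrix emulating a pan-genome
#' presence/absence study of multipartite versus unipartite genomes:
#' background gene families present at a shared rate in both classes, a
#' "set 1" block enriched in the multipartite class, a mirrored "set 2" block
#' enriched in the unipartite class, and independent Bernoulli bit-flip noise
#' applied after planting. Optionally, toy protein families with controlled
#' within/between-family identity are emitted to exercise homology collapsing.
#'
#' The defaults (30 + 30 genomes, 500 background families at presence
#' probability 0.3, 20 + 20 planted families at 0.95/0.05, 2% flip noise)
#' mimic the scale of a ~40-genome comparative study while leaving the
#' planted signal recoverable.
#'
#' @param n_multipartite,n_unipartite genomes per class.
#' @param n_background non-informative families, present at `p_background`
#'   in both classes.
#' @param p_background background presence probability, in \[0,1\].
#' @param n_set1 families enriched in multipartite genomes.
#' @param n_set2 families enriched in unipartite genomes.
#' @param q_high presence probability in the enriched class.
#' @param q_low presence probability in the depleted class; must be < q_high
#'   when any families are planted.
#' @param epsilon independent bit-flip probability applied to every entry
#'   after planting.
#' @param seed integer RNG seed; identical spec + seed gives bit-identical
#'   output.
#' @param emit_proteomes whether [generate_proteomes()] may be called on this
#'   spec.
#' @param within_family_identity minimum fractional identity of each family
#'   member to its family ancestor, in (0.3, 1\].
#' @param between_family_identity maximum fractional identity between
#'   ancestors of different families, in \[0, 0.3).
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_multipartite = 30, n_unipartite = 30,
                           n_background = 500, p_background = 0.3,
                           n_set1 = 20, n_set2 = 20,
                           q_high = 0.95, q_low = 0.05,
                           epsilon = 0.02, seed = 1L,
                           emit_proteomes = FALSE,
                           within_family_identity = 0.9,
                           between_family_identity = 0.1) {
  for (nm in c("n_multipartite", "n_unipartite", "n_background",
               "n_set1", "n_set2"))
    if (!is_count(get(nm))) stopf("%s must be a non-negative integer", nm)
  for (nm in c("p_background", "q_high", "q_low", "epsilon"))
    if (!is_prob(get(nm))) stopf("%s must be a probability in [0,1]", nm)
  if ((n_set1 + n_set2) > 0 && !(q_high > q_low))
    stopf("q_high must exceed q_low when planted families are requested")
  if (!(within_family_identity > 0.3 && within_family_identity <= 1))
    stopf("within_family_identity must lie in (0.3, 1]")
  if (!(between_family_identity >= 0 && between_family_identity < 0.3))
    stopf("between_family_identity must lie in [0, 0.3)")
  structure(list(
    n_multipartite = as.integer(n_multipartite),
    n_unipartite = as.integer(n_unipartite),
    n_background = as.integer(n_background),
    p_background = p_background,
    n_set1 = as.integer(n_set1), n_set2 = as.integer(n_set2),
    q_high = q_high, q_low = q_low, epsilon = epsilon,
    seed = as.integer(seed),
    emit_proteomes = isTRUE(emit_proteomes),
    within_family_identity = within_family_identity,
    between_family_identity = between_family_identity
  ), class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(paste0(
    "synthetic_spec: %d multipartite + %d unipartite genomes\n",
    "  %d background families (p = %.2f), %d set-1 + %d set-2 planted",
    " (q = %.2f / %.2f)\n  flip noise epsilon = %.3f, seed = %d\n"),
    x$n_multipartite, x$n_unipartite, x$n_background, x$p_background,
    x$n_set1, x$n_set2, x$q_high, x$q_low, x$epsilon, x$seed))
  invisible(x)
}

#' Generate a planted-signal presence/absence matrix
#'
#' Entries are drawn family by family: a set-1 column is Bernoulli(q_high)
#' for multipartite rows and Bernoulli(q_low) for unipartite rows, a set-2
#' column is the mirror image, and a background column is
#' Bernoulli(p_background) everywhere. Every bit is then flipped
#' independently with probability `epsilon`. Because noise is applied after
#' planting, the returned ground truth is exact.
#'
#' Each multipartite genome `Mi` is paired with unipartite genome `Ui`
#' (up to the smaller class size), giving downstream code a closest-relative
#' pairing for the differential-matrix variant.
#'
#' @param spec a [synthetic_spec()].
#' @return a list with elements `matrix` (a [presence_matrix()]) and
#'   `truth` (class `ground_truth`: `set1_gene_ids`, `set2_gene_ids`,
#'   `background_gene_ids`, `label_vector`).
#' @export
generate_matrix <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n_r <- spec$n_multipartite + spec$n_unipartite
  n_c <- spec$n_background + spec$n_set1 + spec$n_set2
  g_ids <- c(sprintf("M%02d", seq_len(spec$n_multipartite)),
             sprintf("U%02d", seq_len(spec$n_unipartite)))
  phen <- rep(c("multipartite", "unipartite"),
              c(spec$n_multipartite, spec$n_unipartite))
  set1_ids <- if (spec$n_set1) sprintf("set1g%04d", seq_len(spec$n_set1)) else character()
  set2_ids <- if (spec$n_set2) sprintf("set2g%04d", seq_len(spec$n_set2)) else character()
  bg_ids <- if (spec$n_background) sprintf("bgg%05d", seq_len(spec$n_background)) else character()
  fam_ids <- c(set1_ids, set2_ids, bg_ids)

  is_multi <- phen == "multipartite"
  p_col <- function(p_m, p_u) ifelse(is_multi, p_m, p_u)
  set.seed(derive_seed(spec$seed, "matrix"))
  cols <- vector("list", n_c)
  k <- 0
  for (i in seq_len(spec$n_set1)) {
    k <- k + 1; cols[[k]] <- stats::rbinom(n_r, 1, p_col(spec$q_high, spec$q_low))
  }
  for (i in seq_len(spec$n_set2)) {
    k <- k + 1; cols[[k]] <- stats::rbinom(n_r, 1, p_col(spec$q_low, spec$q_high))
  }
  for (i in seq_len(spec$n_background)) {
    k <- k + 1; cols[[k]] <- stats::rbinom(n_r, 1, spec$p_background)
  }
  bits <- if (n_c) do.call(cbind, cols) else matrix(integer(), n_r, 0)
  if (spec$epsilon > 0 && n_c) {
    flips <- matrix(stats::rbinom(n_r * n_c, 1, spec$epsilon), n_r, n_c)
    bits <- abs(bits - flips)
  }
  dimnames(bits) <- list(g_ids, fam_ids)

  n_pair <- min(spec$n_multipartite, spec$n_unipartite)
  pairing <- if (n_pair) stats::setNames(sprintf("U%02d", seq_len(n_pair)),
                                         sprintf("M%02d", seq_len(n_pair)))
             else NULL
  pm <- presence_matrix(bits, phen, paired_relative = pairing)
  truth <- structure(list(
    set1_gene_ids = set1_ids,
    set2_gene_ids = set2_ids,
    background_gene_ids = bg_ids,
    label_vector = stats::setNames(pm$labels, g_ids)
  ), class = "ground_truth")
  list(matrix = pm, truth = truth)
}

# Amino-acid alphabet used for toy proteomes.
AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

random_protein <- function(len) paste(sample(AA20, len, replace = TRUE),
                                      collapse = "")

# Positional identity of two equal-handling sequences (truncated to the
# shorter); toy sequences are substitution-only so no alignment is needed.
positional_identity <- function(a, b) {
  la <- nchar(a); lb <- nchar(b)
  n <- min(la, lb)
  ca <- substring(a, 1:n, 1:n); cb <- substring(b, 1:n, 1:n)
  sum(ca == cb) / max(la, lb)
}

mutate_protein <- function(seq, n_sub) {
  if (n_sub == 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(length(chars), n_sub)
  for (p in pos) chars[p] <- sample(setdiff(AA20, chars[p]), 1)
  paste(chars, collapse = "")
}

#' Generate toy proteomes realizing a synthetic presence matrix
#'
#' For every gene family an ancestor protein (length 80-120 aa) is drawn;
#' ancestors of different families are rejection-sampled until all pairwise
#' identities fall below `between_family_identity`. A genome carries a
#' member of a family iff the matrix bit is 1; each member is the ancestor
#' with point substitutions only, so its identity to the ancestor is exactly
#' `within_family_identity` (rounded up to the nearest whole residue).
#' Planted (set-1/set-2) genes are annotated "hypothetical protein" so they
#' must be re-grouped by sequence similarity downstream; background genes
#' carry unique names and bypass similarity clustering.
#'
#' @param spec a [synthetic_spec()] with `emit_proteomes = TRUE`.
#' @param matrix optionally, the result of [generate_matrix()] on the same
#'   spec (recomputed if omitted).
#' @param max_retries rejection-sampling bound per ancestor.
#' @return list with `records` (list of [genome_record()]), plus the
#'   `matrix` and `truth` the proteomes realize.
#' @export
generate_proteomes <- function(spec, matrix = NULL, max_retries = 100) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!spec$emit_proteomes)
    stopf("spec does not request proteomes (emit_proteomes = FALSE)")
  gen <- matrix %||% generate_matrix(spec)
  pm <- gen$matrix; truth <- gen$truth
  fams <- family_ids(pm)
  set.seed(derive_seed(spec$seed, "proteomes"))

  ancestors <- character(0)
  for (f in fams) {
    ok <- FALSE
    for (try in seq_len(max_retries)) {
      cand <- random_protein(sample(80:120, 1))
      if (all(vapply(ancestors, positional_identity, 0, b = cand) <
              spec$between_family_identity)) { ok <- TRUE; break }
    }
    if (!ok) stopf("could not draw an ancestor for family %s below %.2f identity after %d retries",
                   f, spec$between_family_identity, max_retries)
    ancestors[f] <- cand
  }

  planted <- c(truth$set1_gene_ids, truth$set2_gene_ids)
  records <- lapply(genome_ids(pm), function(g) {
    present <- fams[pm$bits[g, ] == 1L]
    genes <- lapply(present, function(f) {
      len <- nchar(ancestors[f])
      n_sub <- floor((1 - spec$within_family_identity) * len)
      list(gene_id = paste0(g, "_", f),
           gene_name = if (f %in% planted) "hypothetical protein" else
                       paste0("nam_", f),
           sequence = mutate_protein(ancestors[f], n_sub))
    })
    genome_record(
      genome_id = g,
      phenotype = pm$phenotype[match(g, genome_ids(pm))],
      genes = data.frame(
        gene_id = vapply(genes, `[[`, "", "gene_id"),
        gene_name = vapply(genes, `[[`, "", "gene_name"),
        sequence = vapply(genes, `[[`, "", "sequence"),
        stringsAsFactors = FALSE),
      paired_relative_id = unname(pm$paired_relative[g])
    )
  })
  list(records = records, matrix = pm, truth = truth)
}

#' Randomly permute phenotype labels of a presence matrix
#'
#' Null-model helper: genome rows keep their gene content but phenotype
#' labels are reassigned by a uniform random permutation, preserving class
#' counts. A classifier benchmarked on a permuted matrix should show MCC
#' near 0 (chance-level prediction).
#'
#' @param pm a [presence_matrix()]
#' @param seed integer seed
#' @return a `presence_matrix` with permuted labels
#' @export
permute_labels <- function(pm, seed) {
  stopifnot(inherits(pm, "presence_matrix"))
  if (nrow(pm$bits) == 0) stopf("empty matrix")
  set.seed(derive_seed(seed, "permute-labels"))
  perm <- sample(nrow(pm$bits))
  presence_matrix(pm$bits, pm$phenotype[perm], positive = pm$positive)
}

#' Write synthetic proteomes to FASTA + feature-table TSV
#'
#' One multi-FASTA of protein sequences per genome
#' (`<dir>/<genome_id>.faa`), one combined feature table
#' (`<dir>/features.tsv`: genome_id, gene_id, gene_name, product) and one
#' phenotype table (`<dir>/phenotypes.tsv`: genome_id, phenotype,
#' paired_relative_id).
#'
#' @param records list of [genome_record()]
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
write_proteomes <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  feat <- do.call(rbind, lapply(records, function(r) {
    data.frame(genome_id = r$genome_id,
               gene_id = r$genes$gene_id,
               gene_name = r$genes$gene_name,
               product = r$genes$gene_name,
               stringsAsFactors = FALSE)
  }))
  write_tsv(feat, file.path(dir, "features.tsv"))
  phen <- data.frame(
    genome_id = vapply(records, `[[`, "", "genome_id"),
    phenotype = vapply(records, `[[`, "", "phenotype"),
    paired_relative_id = vapply(records, function(r)
      r$paired_relative_id %||% NA_character_, ""),
    stringsAsFactors = FALSE)
  write_tsv(phen, file.path(dir, "phenotypes.tsv"))
  for (r in records) {
    seqs <- Biostrings::AAStringSet(stats::setNames(r$genes$sequence,
                                                    r$genes$gene_id))
    Biostrings::writeXStringSet(seqs, file.path(dir, paste0(r$genome_id, ".faa")))
  }
  invisible(dir)
}
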