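#' BLAST-style homology acceptance thresholds
#'
#' A candidate hit links two hypothetical-protein genes when its E-value is
#' at most `evalue_max`, its query coverage at least `coverage_min` and its
#' fractional identity at least `identity_min`. Defaults follow the common
#' comparative-genomics practice of E <= 1e-5 with >70% query coverage and
#' >30% identity.
#'
#' @param evalue_max maximum E-value (> 0).
#' @param coverage_min minimum aligned fraction of the query length, \[0,1\].
#' @param identity_min minimum fractional identity, \[0,1\].
#' @return an object of class `homology_thresholds`.
#' @export
homology_thresholds <- function(evalue_max = 1e-5, coverage_min = 0.70,
                                identity_min = 0.30) {
  if (!(is.numeric(evalue_max) && evalue_max > 0))
    stopf("evalue_max must be > 0")
  if (!is_prob(coverage_min) || !is_prob(identity_min))
    stopf("coverage_min and identity_min must lie in [0,1]")
  structure(list(evalue_max = evalue_max, coverage_min = coverage_min,
                 identity_min = identity_min),
            class = "homology_thresholds")
}

#' Internal pairwise-alignment homology backend
#'
#' All-vs-all local protein alignment (Smith-Waterman via
#' [Biostrings::pairwiseAlignment()], BLOSUM62). Identity is computed over
#' the aligned region (identical positions / alignment length) and coverage
#' as aligned query residues / query length. No E-value is estimated: the
#' reported E-value is 0, so filtering rests on the identity and coverage
#' gates. Suitable for moderate numbers of sequences; plug in
#' [homology_backend_blast()] for large real datasets.
#'
#' @param sequences named character vector of protein sequences.
#' @return data.frame (query, subject, evalue, identity, query_coverage),
#'   one row per ordered pair with a reportable alignment.
#' @export
homology_backend_align <- function(sequences) {
  ids <- names(sequences)
  n <- length(ids)
  if (n < 2)
    return(data.frame(query = character(), subject = character(),
                      evalue = numeric(), identity = numeric(),
                      query_coverage = numeric()))
  subj <- Biostrings::AAStringSet(sequences)
  rows <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    js <- (i + 1):n
    aln <- Biostrings::pairwiseAlignment(
      rep(Biostrings::AAStringSet(sequences[i]), length(js)), subj[js],
      type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 0.5)
    idt <- Biostrings::pid(aln, type = "PID1") / 100
    qaln <- Biostrings::nchar(Biostrings::pattern(aln)) # aligned query span
    cov_q <- qaln / nchar(sequences[i])              # coverage of i as query
    cov_s <- qaln / nchar(sequences[js])             # coverage of j as query
    rows[[i]] <- data.frame(
      query = c(rep(ids[i], length(js)), ids[js]),
      subject = c(ids[js], rep(ids[i], length(js))),
      evalue = 0,
      identity = c(idt, idt),
      query_coverage = c(cov_q, cov_s),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' External BLAST+ homology backend
#'
#' Shells out to `makeblastdb` and `blastp` (must be on PATH) for an
#' all-vs-all protein search and parses tabular output
#' (qseqid sseqid evalue pident qcovs). Self-hits are dropped.
#'
#' @param sequences named character vector of protein sequences.
#' @return data.frame (query, subject, evalue, identity, query_coverage).
#' @export
homology_backend_blast <- function(sequences) {
  if (Sys.which("blastp") == "" || Sys.which("makeblastdb") == "")
    stopf("blastp/makeblastdb not found on PATH")
  td <- tempfile("blastdb"); dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  fa <- file.path(td, "prot.faa")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), fa)
  db <- file.path(td, "db")
  system2("makeblastdb", c("-in", fa, "-dbtype", "prot", "-out", db),
          stdout = FALSE, stderr = FALSE)
  out <- file.path(td, "hits.tsv")
  system2("blastp", c("-query", fa, "-db", db, "-outfmt",
                      shQuote("6 qseqid sseqid evalue pident qcovs"),
                      "-out", out),
          stdout = FALSE, stderr = FALSE)
  if (!file.size(out))
    return(data.frame(query = character(), subject = character(),
                      evalue = numeric(), identity = numeric(),
                      query_coverage = numeric()))
  hits <- utils::read.table(out, sep = "\t", stringsAsFactors = FALSE)
  names(hits) <- c("query", "subject", "evalue", "identity", "query_coverage")
  hits$identity <- hits$identity / 100
  hits$query_coverage <- hits$query_coverage / 100
  hits[hits$query != hits$subject, ]
}

#' Collapse genes into families by name and single-linkage similarity
#'
#' Named genes form one family per distinct (case-insensitive) gene name,
#' with no sequence comparison. Hypothetical-protein genes are compared
#' all-vs-all through the chosen homology backend; an undirected edge joins
#' two genes when a hit passes all three thresholds in at least one search
#' direction, and families are the connected components of that graph
#' (single linkage). Hypothetical genes with no passing hit become
#' singleton families.
#'
#' @param records list of [genome_record()].
#' @param thresholds a [homology_thresholds()].
#' @param backend function mapping a named character vector of sequences to
#'   a hit table (query, subject, evalue, identity, query_coverage);
#'   default [homology_backend_align()].
#' @return data.frame with one row per gene:
#'   family_id, display_name, genome_id, gene_id.
#' @export
cluster_hypothetical <- function(records, thresholds = homology_thresholds(),
                                 backend = homology_backend_align) {
  stopifnot(inherits(thresholds, "homology_thresholds"))
  all_genes <- do.call(rbind, lapply(records, function(r)
    data.frame(genome_id = r$genome_id, gene_id = r$genes$gene_id,
               gene_name = r$genes$gene_name, sequence = r$genes$sequence,
               stringsAsFactors = FALSE)))
  # gene ids must be globally unique for graph vertices; qualify by genome
  all_genes$uid <- paste(all_genes$genome_id, all_genes$gene_id, sep = "::")
  hyp <- all_genes[is_hypothetical(all_genes$gene_name), ]
  named <- all_genes[!is_hypothetical(all_genes$gene_name), ]

  fam_rows <- list()
  if (nrow(named)) {
    key <- tolower(trimws(named$gene_name))
    uk <- sort(unique(key))
    fam_id <- stats::setNames(sprintf("nfam%05d", seq_along(uk)), uk)
    fam_rows$named <- data.frame(
      family_id = unname(fam_id[key]),
      display_name = named$gene_name,
      genome_id = named$genome_id, gene_id = named$gene_id,
      stringsAsFactors = FALSE)
  }

  if (nrow(hyp)) {
    noseq <- is.na(hyp$sequence) | !nzchar(hyp$sequence)
    if (any(noseq))
      stopf("hypothetical protein gene(s) lack a sequence: %s",
            paste(utils::head(hyp$gene_id[noseq], 5), collapse = ", "))
    seqs <- stats::setNames(hyp$sequence, hyp$uid)
    hits <- backend(seqs)
    pass <- hits[hits$evalue <= thresholds$evalue_max &
                 hits$identity >= thresholds$identity_min &
                 hits$query_coverage >= thresholds$coverage_min, ,
                 drop = FALSE]
    g <- igraph::make_empty_graph(n = 0, directed = FALSE)
    g <- igraph::add_vertices(g, nrow(hyp), name = hyp$uid)
    if (nrow(pass)) {
      e <- unique(t(apply(cbind(pass$query, pass$subject), 1, sort)))
      g <- igraph::add_edges(g, rbind(match(e[, 1], hyp$uid),
                                      match(e[, 2], hyp$uid)))
    }
    comp <- igraph::components(g)$membership
    # deterministic, order-invariant family ids: number components by their
    # lexicographically smallest member
    key_of <- tapply(hyp$uid, comp[hyp$uid], min)
    rank_of <- stats::setNames(rank(key_of), names(key_of))
    fam_rows$hyp <- data.frame(
      family_id = sprintf("hfam%05d", rank_of[as.character(comp[hyp$uid])]),
      display_name = "hypothetical protein",
      genome_id = hyp$genome_id, gene_id = hyp$gene_id,
      stringsAsFactors = FALSE)
  }
  fams <- do.call(rbind, fam_rows)
  rownames(fams) <- NULL
  fams[order(fams$family_id, fams$genome_id, fams$gene_id), ]
}

#' Build the binary presence/absence matrix from records and families
#'
#' bit(genome, family) = 1 iff the genome carries at least one member of
#' the family.
#'
#' @param records list of [genome_record()].
#' @param families family table from [cluster_hypothetical()].
#' @param positive phenotype coded 1; default multipartite.
#' @return a [presence_matrix()]
#' @export
build_presence_matrix <- function(records, families,
                                  positive = c("multipartite", "unipartite")) {
  positive <- match.arg(positive)
  n_genes <- sum(vapply(records, function(r) nrow(r$genes), 0L))
  if (nrow(families) != n_genes)
    stopf("families must partition all genes: %d family rows vs %d genes",
          nrow(families), n_genes)
  g_ids <- vapply(records, `[[`, "", "genome_id")
  f_ids <- sort(unique(families$family_id))
  bits <- matrix(0L, length(g_ids), length(f_ids),
                 dimnames = list(g_ids, f_ids))
  idx <- cbind(match(families$genome_id, g_ids),
               match(families$family_id, f_ids))
  bits[idx] <- 1L
  phen <- stats::setNames(vapply(records, `[[`, "", "phenotype"), g_ids)
  pairing <- unlist(lapply(records, function(r)
    if (!is.null(r$paired_relative_id))
      stats::setNames(r$paired_relative_id, r$genome_id)))
  pm <- presence_matrix(bits, phen, paired_relative = pairing,
                        positive = positive)
  attr(pm, "display_name") <- stats::setNames(
    families$display_name[match(f_ids, families$family_id)], f_ids)
  pm
}

#' Keep only families differentially present within relative pairs
#'
#' Restricts the matrix to the families for which at least one
#' (multipartite, paired unipartite relative) genome pair disagrees --
#' i.e. the gene is present in the multipartite genome but absent in its
#' closest unipartite relative, or vice versa. Rows are unchanged.
#'
#' @param pm a [presence_matrix()].
#' @param pairing named character vector (multipartite id -> unipartite id);
#'   defaults to the pairing stored in `pm`.
#' @return a `presence_matrix` with the retained columns.
#' @export
filter_differential <- function(pm, pairing = NULL) {
  pairing <- pairing %||% pm$paired_relative
  if (is.null(pairing) || !length(pairing))
    stopf("no multipartite-unipartite pairing available")
  unknown <- setdiff(c(names(pairing), pairing), genome_ids(pm))
  if (length(unknown))
    stopf("pairing references unknown genome(s): %s",
          paste(unknown, collapse = ", "))
  m_bits <- pm$bits[names(pairing), , drop = FALSE]
  u_bits <- pm$bits[unname(pairing), , drop = FALSE]
  keep <- colSums(m_bits != u_bits) > 0
  pm$bits <- pm$bits[, keep, drop = FALSE]
  pm$paired_relative <- pairing
  pm
}

#' Write the family membership table as TSV
#' @param families family table from [cluster_hypothetical()].
#' @param path output file.
#' @export
write_families_tsv <- function(families, path) {
  write_tsv(families[, c("family_id", "genome_id", "gene_id",
                         "display_name")], path)
}
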