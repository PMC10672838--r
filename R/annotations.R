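#' A single genome's annotation record
#'
#' @param genome_id genome identifier.
#' @param phenotype "multipartite" or "unipartite".
#' @param genes data.frame with columns `gene_id`, `gene_name` (the literal
#'   string "hypothetical protein" marks genes that must be grouped by
#'   sequence similarity rather than by name) and optionally `sequence`
#'   (protein sequence; NA allowed for named genes).
#' @param paired_relative_id optional id of the genome's closest relative of
#'   the opposite genome architecture.
#' @return an object of class `genome_record`.
#' @export
genome_record <- function(genome_id, phenotype, genes,
                          paired_relative_id = NULL) {
  if (!phenotype %in% c("multipartite", "unipartite"))
    stopf("phenotype of %s must be 'multipartite' or 'unipartite', got '%s'",
          genome_id, phenotype)
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "gene_name") %in% names(genes)))
  if (!"sequence" %in% names(genes)) genes$sequence <- NA_character_
  if (anyDuplicated(genes$gene_id))
    stopf("duplicate gene_id in genome %s: %s", genome_id,
          genes$gene_id[duplicated(genes$gene_id)][1])
  if (is.null(paired_relative_id) || is.na(paired_relative_id))
    paired_relative_id <- NULL
  structure(list(genome_id = genome_id, phenotype = phenotype,
                 genes = genes, paired_relative_id = paired_relative_id),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("genome_record %s (%s): %d genes, %d hypothetical%s\n",
              x$genome_id, x$phenotype, nrow(x$genes),
              sum(is_hypothetical(x$genes$gene_name)),
              if (is.null(x$paired_relative_id)) ""
              else paste0(", paired with ", x$paired_relative_id)))
  invisible(x)
}

is_hypothetical <- function(gene_name) {
  tolower(trimws(gene_name)) == "hypothetical protein"
}

#' Read genome annotations from feature table + FASTA + phenotype table
#'
#' @param feature_table_path TSV with columns `genome_id`, `gene_id`,
#'   `gene_name` (and optionally `product`, used when `gene_name` is empty).
#' @param fasta_path one or more protein multi-FASTA files whose sequence
#'   names are gene ids; may be NULL when no similarity clustering is needed.
#'   FASTA entries whose id is absent from the feature table are ignored
#'   with a warning.
#' @param phenotype_table_path TSV with columns `genome_id`, `phenotype`
#'   and optionally `paired_relative_id`. Every genome of the feature table
#'   must appear here.
#' @return list of [genome_record()]
#' @export
read_annotations <- function(feature_table_path, fasta_path = NULL,
                             phenotype_table_path) {
  feat <- read_tsv(feature_table_path)
  need <- c("genome_id", "gene_id", "gene_name")
  if (!all(need %in% names(feat)))
    stopf("feature table must have columns: %s", paste(need, collapse = ", "))
  if ("product" %in% names(feat)) {
    blank <- !nzchar(trimws(feat$gene_name)) | is.na(feat$gene_name)
    feat$gene_name[blank] <- feat$product[blank]
  }
  phen <- read_tsv(phenotype_table_path)
  if (!all(c("genome_id", "phenotype") %in% names(phen)))
    stopf("phenotype table must have columns genome_id, phenotype")
  bad <- setdiff(unique(phen$phenotype), c("multipartite", "unipartite"))
  if (length(bad))
    stopf("invalid phenotype value(s): %s", paste(bad, collapse = ", "))
  missing <- setdiff(unique(feat$genome_id), phen$genome_id)
  if (length(missing))
    stopf("genome(s) in feature table missing from phenotype table: %s",
          paste(missing, collapse = ", "))

  seqs <- NULL
  if (!is.null(fasta_path)) {
    sets <- lapply(fasta_path, Biostrings::readAAStringSet)
    aa <- do.call(c, sets)
    # keep only the first whitespace-delimited token of each header
    names(aa) <- sub("\\s.*$", "", names(aa))
    unknown <- setdiff(names(aa), feat$gene_id)
    if (length(unknown)) {
      warnf("%d FASTA sequence(s) not in the feature table were ignored (e.g. %s)",
            length(unknown), unknown[1])
      aa <- aa[setdiff(names(aa), unknown)]
    }
    seqs <- stats::setNames(as.character(aa), names(aa))
  }

  lapply(split(feat, feat$genome_id), function(g) {
    genes <- data.frame(gene_id = g$gene_id, gene_name = g$gene_name,
                        stringsAsFactors = FALSE)
    genes$sequence <- if (is.null(seqs)) NA_character_ else
      unname(seqs[genes$gene_id])
    p <- phen[match(g$genome_id[1], phen$genome_id), ]
    genome_record(g$genome_id[1], p$phenotype, genes,
                  paired_relative_id = if ("paired_relative_id" %in% names(p))
                    p$paired_relative_id else NULL)
  })
}

#' Extract a gene feature table from a GFF3 file
#'
#' Convenience reader for GFF3 annotation: CDS/gene features are reduced to
#' (genome_id, gene_id, gene_name) rows using the `ID`/`locus_tag`,
#' `gene` and `product` attributes. Requires the rtracklayer package.
#'
#' @param gff_path GFF3 file.
#' @param genome_id genome identifier to stamp on every row.
#' @return data.frame with columns genome_id, gene_id, gene_name.
#' @export
read_gff3_genes <- function(gff_path, genome_id) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stopf("reading GFF3 requires the rtracklayer package")
  gr <- rtracklayer::import(gff_path)
  keep <- as.character(gr$type) %in% c("gene", "CDS")
  gr <- gr[keep]
  md <- as.data.frame(gr)
  gid <- if ("locus_tag" %in% names(md)) md$locus_tag else md$ID
  gname <- rep(NA_character_, length(gr))
  if ("gene" %in% names(md)) gname <- md$gene
  if ("product" %in% names(md)) {
    blank <- is.na(gname) | !nzchar(gname)
    gname[blank] <- md$product[blank]
  }
  gname[is.na(gname) | !nzchar(gname)] <- "hypothetical protein"
  out <- data.frame(genome_id = genome_id, gene_id = gid,
                    gene_name = gname, stringsAsFactors = FALSE)
  out[!duplicated(out$gene_id), ]
}
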