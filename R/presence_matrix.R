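#' Binary genomes x gene-families presence/absence matrix
#'
#' The central container of the package: a binary matrix with genomes as rows
#' and gene families as columns, plus a phenotype label per genome and an
#' optional pairing of each multipartite genome with its closest unipartite
#' relative. By default the multipartite phenotype is coded 1 (the positive
#' class of every downstream metric) and unipartite 0; pass
#' `positive = "unipartite"` to flip the coding.
#'
#' @param bits binary matrix (0/1), rows named by genome, columns by family.
#' @param phenotype character vector ("multipartite"/"unipartite"), one per
#'   row of `bits`, in row order or named by genome id.
#' @param paired_relative optional named character vector mapping multipartite
#'   genome ids to the id of their closest unipartite relative.
#' @param positive which phenotype is coded 1 and treated as the positive
#'   class; default "multipartite".
#' @return an object of class `presence_matrix`: a list with elements
#'   `bits` (integer matrix), `phenotype` (character), `labels` (integer 0/1),
#'   `positive`, `paired_relative`.
#' @export
presence_matrix <- function(bits, phenotype, paired_relative = NULL,
                            positive = c("multipartite", "unipartite")) {
  positive <- match.arg(positive)
  bits <- as.matrix(bits)
  if (is.null(rownames(bits)))
    rownames(bits) <- sprintf("G%03d", seq_len(nrow(bits)))
  if (is.null(colnames(bits)))
    colnames(bits) <- sprintf("fam%05d", seq_len(ncol(bits)))
  if (anyDuplicated(rownames(bits))) stopf("duplicate genome ids")
  if (anyDuplicated(colnames(bits))) stopf("duplicate family ids")
  storage.mode(bits) <- "integer"
  if (!all(bits %in% c(0L, 1L))) stopf("matrix entries must be 0 or 1")

  if (!is.null(names(phenotype))) {
    miss <- setdiff(rownames(bits), names(phenotype))
    if (length(miss)) stopf("no phenotype for genome(s): %s",
                            paste(miss, collapse = ", "))
    phenotype <- unname(phenotype[rownames(bits)])
  }
  if (length(phenotype) != nrow(bits))
    stopf("phenotype length (%d) != number of genomes (%d)",
          length(phenotype), nrow(bits))
  bad <- setdiff(unique(phenotype), c("multipartite", "unipartite"))
  if (length(bad))
    stopf("phenotype values must be 'multipartite' or 'unipartite', got: %s",
          paste(bad, collapse = ", "))
  if (!is.null(paired_relative)) {
    unknown <- setdiff(c(names(paired_relative), paired_relative),
                       rownames(bits))
    if (length(unknown))
      stopf("paired_relative references unknown genome(s): %s",
            paste(unknown, collapse = ", "))
  }
  structure(list(
    bits = bits,
    phenotype = phenotype,
    labels = stats::setNames(as.integer(phenotype == positive),
                             rownames(bits)),
    positive = positive,
    paired_relative = paired_relative
  ), class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("presence_matrix: %d genomes x %d gene families\n",
              nrow(x$bits), ncol(x$bits)))
  cat(sprintf("  phenotypes: %d multipartite, %d unipartite (positive class: %s)\n",
              sum(x$phenotype == "multipartite"),
              sum(x$phenotype == "unipartite"), x$positive))
  cat(sprintf("  density: %.3f\n", mean(x$bits)))
  if (!is.null(x$paired_relative))
    cat(sprintf("  %d multipartite-unipartite pairs\n",
                length(x$paired_relative)))
  invisible(x)
}

#' @export
dim.presence_matrix <- function(x) dim(x$bits)

#' Genome and gene-family identifiers of a presence matrix
#' @param pm a [presence_matrix()]
#' @return character vector of ids
#' @export
genome_ids <- function(pm) rownames(pm$bits)

#' @rdname genome_ids
#' @export
family_ids <- function(pm) colnames(pm$bits)

#' Restrict a presence matrix to a subset of families
#' @param pm a [presence_matrix()]
#' @param families character vector of family ids to keep
#' @return a `presence_matrix` with the selected columns, in the given order
#' @export
subset_families <- function(pm, families) {
  miss <- setdiff(families, family_ids(pm))
  if (length(miss)) stopf("unknown family id(s): %s",
                          paste(utils::head(miss, 5), collapse = ", "))
  pm$bits <- pm$bits[, families, drop = FALSE]
  pm
}

#' Write a presence matrix as TSV
#'
#' Layout: one row per genome, one column per gene family, plus a leading
#' `genome_id` column and a final `label` column holding the 0/1 phenotype
#' code (matching the matrix layout used for classifier input).
#'
#' @param pm a [presence_matrix()]
#' @param path output file
#' @export
write_matrix_tsv <- function(pm, path) {
  df <- data.frame(genome_id = genome_ids(pm),
                   pm$bits, check.names = FALSE,
                   stringsAsFactors = FALSE)
  df$label <- pm$labels
  write_tsv(df, path)
}

#' Read a presence matrix from TSV written by [write_matrix_tsv()]
#'
#' @param path TSV file with `genome_id` first, families, then `label` last.
#' @param positive phenotype coded 1 in the file (default multipartite).
#' @return a [presence_matrix()]
#' @export
read_matrix_tsv <- function(path, positive = c("multipartite", "unipartite")) {
  positive <- match.arg(positive)
  df <- read_tsv(path)
  if (!all(c("genome_id", "label") %in% names(df)))
    stopf("matrix TSV must have 'genome_id' and 'label' columns")
  fam_cols <- setdiff(names(df), c("genome_id", "label"))
  bits <- as.matrix(df[, fam_cols, drop = FALSE])
  rownames(bits) <- df$genome_id
  negative <- setdiff(c("multipartite", "unipartite"), positive)
  phen <- ifelse(df$label == 1L, positive, negative)
  presence_matrix(bits, phen, positive = positive)
}

#' Import a Roary gene_presence_absence.csv as a presence matrix
#'
#' Reads the Roary pan-genome dialect: one row per gene family ("Gene"
#' column), 14 fixed annotation columns, then one column per genome whose
#' cells are empty when the family is absent. Phenotypes come from a separate
#' table because Roary knows nothing about them.
#'
#' @param csv_path Roary gene_presence_absence.csv
#' @param phenotype named character vector or two-column data.frame
#'   (genome_id, phenotype) labelling every genome column of the CSV.
#' @param positive phenotype coded 1; default multipartite.
#' @return a [presence_matrix()]
#' @export
read_roary_csv <- function(csv_path, phenotype,
                           positive = c("multipartite", "unipartite")) {
  positive <- match.arg(positive)
  df <- utils::read.csv(csv_path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  fixed <- c("Gene", "Non-unique Gene name", "Annotation", "No. isolates",
             "No. sequences", "Avg sequences per isolate", "Genome Fragment",
             "Order within Fragment", "Accessory Fragment",
             "Accessory Order with Fragment", "QC", "Min group size nuc",
             "Max group size nuc", "Avg group size nuc")
  if (!"Gene" %in% names(df)) stopf("not a Roary gene_presence_absence.csv")
  genome_cols <- setdiff(names(df), fixed)
  bits <- t(apply(df[, genome_cols, drop = FALSE], 1,
                  function(r) as.integer(!is.na(r) & nzchar(r))))
  rownames(bits) <- make.unique(df$Gene)
  bits <- t(bits)  # genomes x families
  rownames(bits) <- genome_cols
  if (is.data.frame(phenotype))
    phenotype <- stats::setNames(phenotype[[2]], phenotype[[1]])
  presence_matrix(bits, phenotype, positive = positive)
}
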