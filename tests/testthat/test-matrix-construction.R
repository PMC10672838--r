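# A stub homology backend lets clustering logic be tested without any
# alignment: hits are declared explicitly.
stub_backend <- function(hits) {
  function(sequences) hits
}

two_genome_records <- function() {
  list(
    genome_record("gA", "multipartite", data.frame(
      gene_id = c("g1", "g2", "g3"),
      gene_name = c("recA", "hypothetical protein", "hypothetical protein"),
      sequence = c(NA, "MKKLLVA", "MKKLLVQ"))),
    genome_record("gB", "unipartite", data.frame(
      gene_id = c("g1", "g2"),
      gene_name = c("recA", "hypothetical protein"),
      sequence = c(NA, "MKKLLVA")))
  )
}

test_that("annotation reading builds one record per genome with phenotypes", {
  d <- withr::local_tempdir()
  feat <- data.frame(genome_id = rep(c("gA", "gB"), each = 3),
                     gene_id = paste0("g", 1:6),
                     gene_name = c("recA", "recB", "recC",
                                   "recA", "recB", "recC"))
  write.table(feat, file.path(d, "features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  phen <- data.frame(genome_id = c("gA", "gB"),
                     phenotype = c("multipartite", "unipartite"),
                     paired_relative_id = c("gB", NA))
  write.table(phen, file.path(d, "phen.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  rec <- read_annotations(file.path(d, "features.tsv"), NULL,
                          file.path(d, "phen.tsv"))
  expect_length(rec, 2)
  expect_identical(vapply(rec, function(r) nrow(r$genes), 0L), c(gA = 3L, gB = 3L))
  expect_identical(rec$gA$paired_relative_id, "gB")
  expect_null(rec$gB$paired_relative_id)

  # invalid phenotype value
  phen_bad <- phen; phen_bad$phenotype[1] <- "diploid"
  write.table(phen_bad, file.path(d, "phen_bad.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_annotations(file.path(d, "features.tsv"), NULL,
                                file.path(d, "phen_bad.tsv")), "diploid")

  # genome missing from the phenotype table
  write.table(phen[1, ], file.path(d, "phen_miss.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_annotations(file.path(d, "features.tsv"), NULL,
                                file.path(d, "phen_miss.tsv")), "gB")

  # FASTA id absent from the feature table is ignored with a warning
  aa <- Biostrings::AAStringSet(c(g1 = "MKV", zz = "MLL"))
  Biostrings::writeXStringSet(aa, file.path(d, "p.faa"))
  expect_warning(read_annotations(file.path(d, "features.tsv"),
                                  file.path(d, "p.faa"),
                                  file.path(d, "phen.tsv")), "ignored")
})

test_that("duplicate gene ids within a genome are rejected", {
  expect_error(genome_record("g", "unipartite", data.frame(
    gene_id = c("a", "a"), gene_name = c("x", "y"))), "duplicate")
})

test_that("identical hypothetical proteins collapse into one family", {
  rec <- two_genome_records()
  fams <- cluster_hypothetical(rec)
  # recA forms one named family across genomes
  named <- fams[fams$display_name == "recA", ]
  expect_identical(sort(named$genome_id), c("gA", "gB"))
  expect_length(unique(named$family_id), 1)
  # gA:g2 and gB:g2 are identical sequences; gA:g3 is one substitution away
  # (identity 6/7 = 86% > 30%, full coverage) so all three link up
  hyp <- fams[fams$display_name == "hypothetical protein", ]
  expect_length(unique(hyp$family_id), 1)
  expect_identical(nrow(hyp), 3L)
})

test_that("single linkage chains A-B and B-C into one family without an A-C hit", {
  rec <- list(genome_record("g1", "multipartite", data.frame(
    gene_id = c("A", "B", "C"),
    gene_name = rep("hypothetical protein", 3),
    sequence = c("MAAA", "MCCC", "MGGG"))))
  hits <- data.frame(
    query = c("g1::A", "g1::B"), subject = c("g1::B", "g1::C"),
    evalue = 1e-20, identity = 0.9, query_coverage = 0.9)
  fams <- cluster_hypothetical(rec, backend = stub_backend(hits))
  expect_length(unique(fams$family_id), 1)
})

test_that("a hit failing any threshold does not link, and a no-hit gene is a singleton", {
  rec <- list(genome_record("g1", "multipartite", data.frame(
    gene_id = c("A", "B", "C"),
    gene_name = rep("hypothetical protein", 3),
    sequence = c("MAAA", "MCCC", "MGGG"))))
  hits <- data.frame(
    query = c("g1::A", "g1::A", "g1::A"),
    subject = c("g1::B", "g1::B", "g1::B"),
    evalue = c(1e-3, 1e-20, 1e-20),            # fails E-value
    identity = c(0.9, 0.2, 0.9),               # fails identity
    query_coverage = c(0.9, 0.9, 0.5))         # fails coverage
  fams <- cluster_hypothetical(rec, backend = stub_backend(hits))
  expect_length(unique(fams$family_id), 3)     # all singletons, incl. C
})

test_that("one passing direction suffices to link a pair", {
  rec <- list(genome_record("g1", "multipartite", data.frame(
    gene_id = c("A", "B"),
    gene_name = rep("hypothetical protein", 2),
    sequence = c("MAAA", "MCCC"))))
  hits <- data.frame(
    query = c("g1::A", "g1::B"), subject = c("g1::B", "g1::A"),
    evalue = c(1e-20, 1e-20), identity = c(0.9, 0.1),
    query_coverage = c(0.9, 0.2))
  fams <- cluster_hypothetical(rec, backend = stub_backend(hits))
  expect_length(unique(fams$family_id), 1)
})

test_that("hypothetical genes without sequences are refused by name", {
  rec <- list(genome_record("g1", "multipartite", data.frame(
    gene_id = "A", gene_name = "hypothetical protein",
    sequence = NA_character_)))
  expect_error(cluster_hypothetical(rec), "A")
})

test_that("clustering is invariant to genome input order", {
  pro <- generate_proteomes(tiny_proteome_spec(seed = 21))
  fams1 <- cluster_hypothetical(pro$records)
  fams2 <- cluster_hypothetical(rev(pro$records))
  key <- function(f) sort(vapply(
    split(paste(f$genome_id, f$gene_id), f$family_id),
    function(v) paste(sort(v), collapse = "|"), ""))
  expect_identical(unname(key(fams1)), unname(key(fams2)))
})

test_that("presence matrix bits reflect family membership", {
  rec <- two_genome_records()
  fams <- cluster_hypothetical(rec)
  pm <- build_presence_matrix(rec, fams)
  expect_identical(dim(pm$bits), c(2L, 2L))    # recA family + one hyp family
  expect_true(all(pm$bits == 1L))              # both genomes carry both
  expect_identical(unname(pm$labels), c(1L, 0L))  # multipartite coded 1

  # a genome with zero genes yields an all-zero row
  rec3 <- c(rec, list(genome_record("gC", "unipartite", data.frame(
    gene_id = character(), gene_name = character(),
    sequence = character()))))
  pm3 <- build_presence_matrix(rec3, fams)
  expect_true(all(pm3$bits["gC", ] == 0L))

  # families must partition the genes
  expect_error(build_presence_matrix(rec, fams[-1, ]), "partition")
})

test_that("proteomes round-trip through clustering to the generating matrix", {
  pro <- generate_proteomes(tiny_proteome_spec(seed = 31))
  fams <- cluster_hypothetical(pro$records)
  ari <- adjusted_rand_index(fams$family_id, true_family_of(fams$gene_id))
  expect_equal(ari, 1.0)
  pm2 <- build_presence_matrix(pro$records, fams)
  # map recovered families back to generating ids and compare bit patterns
  key <- vapply(split(true_family_of(fams$gene_id), fams$family_id),
                function(v) v[1], "")
  m2 <- pm2$bits; colnames(m2) <- unname(key[colnames(m2)])
  m1 <- pro$matrix$bits
  present <- colnames(m1)[colSums(m1) > 0]   # empty families leave no gene
  expect_setequal(colnames(m2), present)
  expect_identical(m1[rownames(m2), sort(colnames(m2))],
                   m2[, sort(colnames(m2))])
})

test_that("the BLAST+ backend reproduces the internal aligner's partition", {
  pro <- generate_proteomes(tiny_proteome_spec(
    seed = 41, n_multipartite = 4, n_unipartite = 4, n_background = 4,
    n_set1 = 2, n_set2 = 2))
  fams_a <- cluster_hypothetical(pro$records)
  fams_b <- cluster_hypothetical(pro$records,
                                 backend = homology_backend_blast)
  key <- function(f) sort(vapply(
    split(paste(f$genome_id, f$gene_id), f$family_id),
    function(v) paste(sort(v), collapse = "|"), ""))
  expect_identical(unname(key(fams_a)), unname(key(fams_b)))
})

test_that("differential filtering keeps exactly the within-pair disagreements", {
  bits <- cbind(all1 = c(1L, 1L, 1L, 1L), all0 = c(0L, 0L, 0L, 0L),
                diff = c(1L, 0L, 1L, 1L),   # pair (m1,u1) disagrees 1/0
                same = c(1L, 1L, 0L, 0L))   # both pairs agree
  rownames(bits) <- c("m1", "u1", "m2", "u2")
  pm <- presence_matrix(bits, c("multipartite", "unipartite",
                                "multipartite", "unipartite"),
                        paired_relative = c(m1 = "u1", m2 = "u2"))
  out <- filter_differential(pm)
  expect_identical(colnames(out$bits), "diff")
  expect_identical(rownames(out$bits), rownames(bits))
  expect_error(filter_differential(pm, c(m1 = "zz")), "unknown")
  pm_nopair <- presence_matrix(bits, pm$phenotype)
  expect_error(filter_differential(pm_nopair), "pairing")
})

test_that("matrix TSV and Roary CSV round-trip into presence matrices", {
  d <- withr::local_tempdir()
  gen <- generate_matrix(tiny_spec(seed = 13))
  path <- file.path(d, "m.tsv")
  write_matrix_tsv(gen$matrix, path)
  back <- read_matrix_tsv(path)
  expect_identical(back$bits, gen$matrix$bits)
  expect_identical(back$labels, gen$matrix$labels)

  roary <- data.frame(
    Gene = c("famA", "famB"), `Non-unique Gene name` = "", Annotation = "",
    `No. isolates` = 2, `No. sequences` = 2,
    `Avg sequences per isolate` = 1, `Genome Fragment` = "",
    `Order within Fragment` = "", `Accessory Fragment` = "",
    `Accessory Order with Fragment` = "", QC = "",
    `Min group size nuc` = "", `Max group size nuc` = "",
    `Avg group size nuc` = "",
    s1 = c("s1_0001", ""), s2 = c("s2_0001", "s2_0002"),
    check.names = FALSE)
  rpath <- file.path(d, "roary.csv")
  write.csv(roary, rpath, row.names = FALSE)
  pm <- read_roary_csv(rpath, c(s1 = "multipartite", s2 = "unipartite"))
  expect_identical(unname(pm$bits["s1", c("famA", "famB")]), c(1L, 0L))
  expect_identical(unname(pm$bits["s2", c("famA", "famB")]), c(1L, 1L))
})

test_that("the GFF3 reader extracts gene ids and names", {
  skip_if_not_installed("rtracklayer")
  d <- withr::local_tempdir()
  gff <- file.path(d, "g.gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\t.\tgene\t1\t900\t.\t+\t.\tID=gene1;locus_tag=LT_001;gene=recA",
    "chr1\t.\tCDS\t1000\t1900\t.\t+\t0\tID=cds2;locus_tag=LT_002;product=hypothetical protein",
    "chr1\t.\tCDS\t2000\t2900\t.\t+\t0\tID=cds3;locus_tag=LT_003;product=DNA polymerase III"),
    gff)
  feat <- read_gff3_genes(gff, "gX")
  expect_identical(nrow(feat), 3L)
  expect_identical(feat$genome_id, rep("gX", 3))
  expect_setequal(feat$gene_id, c("LT_001", "LT_002", "LT_003"))
  expect_identical(feat$gene_name[feat$gene_id == "LT_001"], "recA")
  expect_identical(feat$gene_name[feat$gene_id == "LT_002"],
                   "hypothetical protein")
})
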