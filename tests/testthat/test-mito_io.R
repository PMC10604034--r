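test_that("reading the published feature table yields 38 features, 37 genes", {
  g <- fixture_genome()
  expect_s3_class(g, "mito_genome")
  expect_equal(nrow(g$features), 38)
  expect_equal(sum(g$features$ftype %in% c("PCG", "tRNA", "rRNA")), 37)
  expect_equal(g$genome_length, 16747)
  nd2 <- dplyr::filter(tidy(g), gene == "ND2")
  expect_equal(nd2$size, 1045)
  # isoacceptor disambiguation via the anticodon column
  expect_setequal(
    dplyr::filter(g$features, grepl("^trn[LS]", gene))$gene,
    c("trnL1", "trnL2", "trnS1", "trnS2")
  )
})

test_that("gene-name normalization maps synonym spellings", {
  expect_equal(
    normalize_gene_name(c("NAD1", "COX1", "Cytb", "ATPase6", "D-loop",
                          "12S rRNA", "tRNA-Phe")),
    c("ND1", "COI", "CYTB", "ATP6", "CR", "rrnS", "trnF")
  )
  expect_equal(normalize_gene_name("trnL", anticodon = "CTA"), "trnL1")
  expect_equal(normalize_gene_name("tRNA-Ser", anticodon = "TCA"), "trnS2")
  expect_warning(normalize_gene_name("made_up_gene"), "unrecognized")
})

test_that("feature-table validation catches bad coordinates and duplicates", {
  tab <- tibble::tibble(gene = "CR", start = 10, end = 1, strand = "H")
  expect_error(feature_table_to_genome(tab), "start > end")
  dup <- tibble::tibble(gene = c("ND1", "ND1"), start = c(1, 100),
                        end = c(50, 150), strand = "H")
  expect_error(feature_table_to_genome(dup), "duplicate")
  # size column mismatches warn, never error
  tab2 <- tibble::tibble(gene = "ND1", start = 1, end = 30, strand = "H",
                         size = 99)
  expect_warning(feature_table_to_genome(tab2), "size column")
})

test_that("a one-row table builds a single-feature genome", {
  g <- feature_table_to_genome(
    tibble::tibble(gene = "CR", start = 1, end = 10, strand = "H"))
  expect_equal(nrow(g$features), 1)
  expect_equal(g$genome_length, 10)
})

test_that("feature tables round-trip through write and read", {
  g <- fixture_genome()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(g, path)
  g2 <- read_feature_table(path, accession = g$accession)
  expect_equal(g2$features, g$features)
  expect_equal(g2$genome_length, g$genome_length)
})

test_that("feature extraction honours strand and circular wrap", {
  feats <- tibble::tibble(gene = c("h", "l"), ftype = "other",
                          start = c(1, 1), end = c(3, 3),
                          strand = c("H", "L"), anticodon = NA)
  g <- mito_genome(feats[1, ], sequence = "ATGCCC")
  expect_equal(extract_feature_sequence(g, "h"), "ATG")
  gl <- mito_genome(feats[2, ], sequence = "ATGCCC")
  expect_equal(extract_feature_sequence(gl, "l"), "CAT")
  # wrap through the origin (internal end < start convention)
  wrap <- list(start = 5, end = 2, strand = "H")
  expect_equal(extract_feature_sequence(g, wrap), "CCAT")
  g_noseq <- suppressWarnings(feature_table_to_genome(
    tibble::tibble(gene = "x", start = 1, end = 3, strand = "H")))
  expect_error(extract_feature_sequence(g_noseq, "x"), "state error")
})

test_that("extract on H then reverse-complement equals strand-flipped extract", {
  sim <- default_sim()
  f <- dplyr::slice(sim$genome$features, c(1, 8, 20))
  for (i in seq_len(nrow(f))) {
    fh <- as.list(f[i, ])
    fl <- fh
    fh$strand <- "H"
    fl$strand <- "L"
    expect_equal(revcomp(extract_feature_sequence(sim$genome, fh)),
                 extract_feature_sequence(sim$genome, fl))
  }
})

test_that("GenBank files round-trip through write and read", {
  sim <- default_sim()
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(sim$genome, path)
  g2 <- read_genbank(path)
  expect_equal(g2$accession, sim$genome$accession)
  expect_equal(g2$genome_length, sim$genome$genome_length)
  expect_equal(g2$sequence, sim$genome$sequence)
  expect_equal(g2$features$gene, sim$genome$features$gene)
  expect_equal(g2$features$start, sim$genome$features$start)
  expect_equal(g2$features$end, sim$genome$features$end)
  expect_equal(g2$features$strand, sim$genome$features$strand)
})

test_that("GenBank parser reports malformed input and bad coordinates", {
  p1 <- withr::local_tempfile(fileext = ".gb")
  writeLines(c("NOT_A_LOCUS line", "//"), p1)
  expect_error(read_genbank(p1), "LOCUS")
  p2 <- withr::local_tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       X1 100 bp    DNA     circular     UNA",
    "FEATURES             Location/Qualifiers",
    "     CDS             10..200",
    "                     /gene=\"ND1\"",
    "//"), p2)
  expect_error(read_genbank(p2), "coordinate error")
  # zero features: sequence retained, empty feature list
  p3 <- withr::local_tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       X2 12 bp    DNA     circular     UNA",
    "FEATURES             Location/Qualifiers",
    "ORIGIN",
    "        1 acgtacgtac gt",
    "//"), p3)
  g <- read_genbank(p3)
  expect_equal(nrow(g$features), 0)
  expect_equal(g$sequence, "ACGTACGTACGT")
})

test_that("FASTA write/read round-trips", {
  path <- withr::local_tempfile(fileext = ".fa")
  seqs <- tibble::tibble(name = c("s1", "s2"),
                         sequence = c("ACGTACGT", "TTTTAAAA"))
  write_fasta(seqs, path)
  expect_equal(read_fasta(path), seqs)
})
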