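test_that("base composition handles simple and degenerate inputs", {
  bc <- base_composition("AATT")
  expect_equal(c(bc$pct_A, bc$pct_T, bc$pct_G, bc$pct_C, bc$pct_AT),
               c(50, 50, 0, 0, 100))
  bc2 <- base_composition("ACGT")
  expect_true(all(c(bc2$pct_A, bc2$pct_T, bc2$pct_G, bc2$pct_C) == 25))
  # N's excluded from the denominator
  bc3 <- base_composition("AANN")
  expect_equal(bc3$pct_A, 100)
  expect_equal(bc3$n_N, 2)
  expect_error(base_composition(""), "empty")
})

test_that("skew formulas reproduce the published whole-genome values", {
  sk <- skews(28.09, 26.06, 16.24, 29.56)
  expect_equal(sk$at_skew, 0.037)
  expect_equal(sk$gc_skew, -0.291)
  expect_equal(skews(10, 10, 7, 7), list(at_skew = 0, gc_skew = 0))
  # undefined skew is NA, not zero
  expect_true(is.na(skews(0, 0, 5, 5)$at_skew))
})

test_that("skews are scale-invariant between counts and percentages", {
  withr::with_seed(11, {
    for (i in 1:20) {
      n <- stats::rmultinom(1, 5000, c(0.3, 0.25, 0.2, 0.25))[, 1]
      pct <- 100 * n / sum(n)
      expect_equal(skews(n[1], n[2], n[3], n[4]),
                   skews(pct[1], pct[2], pct[3], pct[4]))
    }
  })
})

test_that("partition stats cover five partitions with consistent lengths", {
  sim <- default_sim()
  ps <- partition_stats(sim$genome)
  expect_equal(ps$partition, c("whole", "PCGs", "rRNAs", "tRNAs", "CR"))
  pl <- partition_lengths(sim$genome)
  expect_equal(ps$length, pl$length[match(ps$partition, pl$partition)])
  expect_equal(ps$length[ps$partition == "whole"], sim$genome$genome_length)
  expect_equal(ps$length[ps$partition == "tRNAs"], 1556)
  # percentage columns sum to 100 within rounding
  sums <- ps$pct_A + ps$pct_T + ps$pct_G + ps$pct_C
  expect_true(all(abs(sums - 100) <= 0.02))
})

test_that("a partition without members is omitted with a warning", {
  g <- mito_genome(
    tibble::tibble(gene = c("ND1", "trnF"), ftype = c("PCG", "tRNA"),
                   start = c(1, 31), end = c(30, 50), strand = "H",
                   anticodon = c(NA, "TTC")),
    sequence = paste(rep("ACGT", 15), collapse = ""))
  warns <- capture_warnings(ps <- partition_stats(g))
  expect_true(any(grepl("no members", warns)))
  expect_false("CR" %in% ps$partition)
  expect_false("rRNAs" %in% ps$partition)
})

test_that("planted composition and skew are recovered within sampling error", {
  # CR with no planted repeat/motifs is pure i.i.d. from its frequency vector
  freqs <- default_partition_freqs()
  freqs$CR <- c(A = 0.33, C = 0.20, G = 0.20, T = 0.27)  # AT-skew 0.10
  sim <- simulate_mitogenome(genome_spec(freqs = freqs, cr_plan = NULL,
                                         seed = 7))
  cr <- dplyr::filter(partition_stats(sim$genome), partition == "CR")
  n <- cr$length
  for (b in c("A", "C", "G", "T")) {
    p <- freqs$CR[[b]]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(cr[[paste0("pct_", b)]] / 100 - p), 3.5 * se)
  }
  # binomial error on the skew via the delta method: sd ~ 2*sqrt(pq)/sqrt(n)/(p+q)
  p_at <- freqs$CR[["A"]] + freqs$CR[["T"]]
  se_skew <- 2 * sqrt(freqs$CR[["A"]] * freqs$CR[["T"]] / p_at^3 / n)
  expect_lt(abs(cr$at_skew - 0.10), 3.5 * se_skew)
})

test_that("codon classification derives stops from length mod 3", {
  g <- mito_genome(
    tibble::tibble(gene = "ND1", ftype = "PCG", start = 1, end = 9,
                   strand = "H", anticodon = NA),
    sequence = "ATGAAATAG")
  cc <- classify_codons(g)
  expect_equal(cc$start_codon, "ATG")
  expect_equal(cc$stop_codon, "TAG")
  expect_equal(cc$stop_class, "complete")
  # remainder 1 -> single base + "--", remainder 2 -> two bases + "-"
  g1 <- mito_genome(
    tibble::tibble(gene = "ND2", ftype = "PCG", start = 1, end = 10,
                   strand = "H", anticodon = NA),
    sequence = "ATGAAACCCT")
  expect_equal(classify_codons(g1)$stop_codon, "T--")
  expect_equal(classify_codons(g1)$stop_class, "incomplete")
  g2 <- mito_genome(
    tibble::tibble(gene = "ND3", ftype = "PCG", start = 1, end = 11,
                   strand = "H", anticodon = NA),
    sequence = "ATGAAACCCTA")
  expect_equal(classify_codons(g2)$stop_codon, "TA-")
  short <- mito_genome(
    tibble::tibble(gene = "ND4", ftype = "PCG", start = 1, end = 5,
                   strand = "H", anticodon = NA),
    sequence = "ATGAA")
  expect_error(classify_codons(short), "shorter than 6")
})

test_that("simulated PCGs report exactly the planted incomplete-stop set", {
  sim <- default_sim()
  cc <- classify_codons(sim$genome)
  truth <- sim$truth$codons
  expect_equal(cc$stop_codon, truth$stop_codon)
  expect_equal(cc$start_codon, truth$start_codon)
  planted_incomplete <- truth$gene[grepl("-", truth$planned_stop)]
  expect_setequal(cc$gene[cc$stop_class == "incomplete"], planted_incomplete)
  # every incomplete stop abuts its downstream neighbour (gap <= 0), as in
  # real mitogenomes where polyadenylation completes the codon
  j <- junction_gaps(sim$genome)
  for (gene in planted_incomplete) {
    expect_lte(j$gap[j$upstream == gene], 0)
  }
  # non-overlapped genes realize their planned codons verbatim
  overlapped <- c("ATP8", "ND4L", "ND5")
  clean <- dplyr::filter(truth, !gene %in% overlapped)
  expect_equal(clean$stop_codon, clean$planned_stop)
  expect_equal(clean$start_codon, clean$planned_start)
})
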