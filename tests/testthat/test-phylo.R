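test_that("K2P distance handles trivial, formula and saturated cases", {
  same <- k2p_distance("ACGTACGT", "ACGTACGT")
  expect_equal(c(same$P, same$Q, same$d), c(0, 0, 0))
  # 100 sites, 10 transitions, 0 transversions
  a <- strrep("A", 100)
  b <- paste0(strrep("G", 10), strrep("A", 90))
  r <- k2p_distance(a, b)
  expect_equal(r$P, 0.1)
  expect_equal(r$Q, 0)
  expect_equal(r$d, -0.5 * log(0.8))
  # saturation: invalid log arguments -> valid FALSE, P/Q still reported
  sat <- k2p_distance(strrep("A", 10), strrep("G", 10))
  expect_false(sat$valid)
  expect_equal(sat$P, 1)
  expect_true(is.na(sat$d))
  # pairwise deletion of ambiguous sites
  r2 <- k2p_distance("ACGTN-", "ACGAAC")
  expect_equal(r2$n_sites, 4)
  expect_error(k2p_distance("NNN", "AAA"), "zero comparable")
  expect_error(k2p_distance("AC", "ACG"), "differ in length")
})

test_that("K2P agrees with an established distance implementation", {
  withr::with_seed(3, {
    tr <- ape::rtree(2)
    tr$edge.length <- c(0.08, 0.08)
    m <- substitution_model("K2P", kappa = 3)
    ev <- evolve_alignment(evol_spec(tr, m, 3000, seed = 3))
  })
  mine <- k2p_distance(ev$alignment$sequence[1], ev$alignment$sequence[2])$d
  bin <- ape::as.DNAbin(t(sapply(strsplit(tolower(ev$alignment$sequence), ""),
                                 identity)))
  rownames(bin) <- ev$alignment$taxon
  ref <- as.numeric(ape::dist.dna(bin, model = "K80"))
  expect_equal(mine, ref, tolerance = 1e-10)
})

test_that("K2P estimate at true distance 0.15 falls within 3 standard errors", {
  tr <- ape::read.tree(text = "(a:0.075,b:0.075);")
  m <- substitution_model("K2P", kappa = 4)
  ev <- evolve_alignment(evol_spec(tr, m, 10000, seed = 11))
  est <- k2p_distance(ev$alignment$sequence[1], ev$alignment$sequence[2])
  expect_lt(abs(est$d - 0.15), 3 * est$se)
})

test_that("PCG concatenation builds a partitioned supermatrix", {
  ga <- tibble::tibble(
    gene = rep(c("ND1", "ND2"), each = 2),
    taxon = rep(c("t1", "t2"), 2),
    sequence = c("ACGTAC", "ACGTAC", "ACGTACGTA", "ACGTACGTT")
  )
  cc <- concatenate_pcgs(ga, gene_order = c("ND1", "ND2"))
  expect_equal(nchar(cc$alignment$sequence), c(15, 15))
  expect_equal(cc$partitions$start, c(1, 7))
  expect_equal(cc$partitions$end, c(6, 15))
  # taxa-order permutation changes row order only
  cc2 <- concatenate_pcgs(ga[c(2, 1, 4, 3), ], gene_order = c("ND1", "ND2"))
  expect_setequal(cc2$alignment$sequence, cc$alignment$sequence)
  # missing pair errors name taxon and gene
  expect_error(concatenate_pcgs(ga[-2, ], gene_order = c("ND1", "ND2")),
               "t2:ND1")
  expect_error(
    concatenate_pcgs(dplyr::mutate(ga, sequence = c("ACGTAC", "ACGT",
                                                    "ACGTACGTA", "ACGTACGTT")),
                     gene_order = c("ND1", "ND2")),
    "unequal lengths")
})

test_that("a 15-taxon 13-gene synthetic set yields 13 partitions", {
  taxa <- paste0("t", 1:15)
  pcgs <- dplyr::filter(mito_vocabulary(), ftype == "PCG")$gene
  ga <- withr::with_seed(2, {
    tidyr::expand_grid(gene = pcgs, taxon = taxa) |>
      dplyr::mutate(sequence = purrr::map_chr(gene, ~ random_seq(30)))
  })
  # within a gene all sequences must be identical length; use one seq per gene
  ga <- ga |>
    dplyr::group_by(gene) |>
    dplyr::mutate(sequence = sequence[1]) |>
    dplyr::ungroup()
  cc <- concatenate_pcgs(ga, gene_order = pcgs)
  expect_equal(nrow(cc$partitions), 13)
  expect_equal(nrow(cc$alignment), 15)
  expect_equal(max(cc$partitions$end), unique(nchar(cc$alignment$sequence)))
})

test_that("neighbor joining is exact on additive matrices", {
  tr <- ape::read.tree(text = "((a:2,b:3):1,c:4,d:6);")
  D <- ape::cophenetic.phylo(tr)
  est <- neighbor_joining(D)
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(est)), 0,
               ignore_attr = TRUE)
  expect_equal(ape::cophenetic.phylo(est)[rownames(D), colnames(D)], D,
               tolerance = 1e-10)
  # 3-taxon star: unique resolution with exact lengths
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  est3 <- neighbor_joining(D3)
  expect_equal(ape::cophenetic.phylo(est3)[c("a", "b", "c"), c("a", "b", "c")],
               D3, tolerance = 1e-10)
  expect_error(neighbor_joining(D3[1:2, 1:2]), ">= 3 taxa")
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)), ">= 3 taxa")
})

test_that("NJ recovers the generating topology from simulated sequences", {
  withr::with_seed(19, {
    true_tree <- ape::rtree(8)
    true_tree$edge.length <- stats::runif(nrow(true_tree$edge), 0.02, 0.15)
  })
  m <- substitution_model("HKY", pi = c(0.3, 0.2, 0.2, 0.3), kappa = 3)
  ev <- evolve_alignment(evol_spec(true_tree, m, 5000, seed = 19))
  est <- neighbor_joining(k2p_matrix(ev$alignment))
  expect_equal(ape::dist.topo(ape::unroot(true_tree), ape::unroot(est)), 0,
               ignore_attr = TRUE)
})

test_that("pruning likelihood matches closed forms and brute force", {
  # JC, two taxa, one site: 1/4 * P_ij(t1 + t2)
  tr <- ape::read.tree(text = "(a:0.1,b:0.2);")
  aln <- tibble::tibble(taxon = c("a", "b"), sequence = c("A", "G"))
  jc <- substitution_model("JC")
  pij <- 0.25 - 0.25 * exp(-4 * 0.3 / 3)
  expect_equal(loglikelihood(tr, aln, jc), log(0.25 * pij), tolerance = 1e-12)
  same <- tibble::tibble(taxon = c("a", "b"), sequence = c("C", "C"))
  pii <- 0.25 + 0.75 * exp(-4 * 0.3 / 3)
  expect_equal(loglikelihood(tr, same, jc), log(0.25 * pii),
               tolerance = 1e-12)
  # 4 taxa, 6 sites vs brute-force enumeration over internal states
  tr4 <- ape::read.tree(text = "((a:0.12,b:0.34):0.08,(c:0.2,d:0.05):0.15);")
  aln4 <- tibble::tibble(taxon = c("a", "b", "c", "d"),
                         sequence = c("ACGTAC", "ACGTTG", "AAGTAC", "GCGTAA"))
  Qjc <- build_gtr_q(rep(1, 6), rep(0.25, 4))
  expect_equal(loglikelihood(tr4, aln4, jc),
               brute_force_loglik(tr4, aln4, Qjc, rep(0.25, 4)),
               tolerance = 1e-9)
  pi <- c(0.35, 0.25, 0.15, 0.25)
  rates <- c(1.2, 4, 0.7, 1.1, 5, 1)
  gtr <- substitution_model("GTR", pi = pi, rates = rates)
  Qg <- build_gtr_q(rates, pi)
  expect_equal(loglikelihood(tr4, aln4, gtr),
               brute_force_loglik(tr4, aln4, Qg, pi),
               tolerance = 1e-9)
})

test_that("gamma mixture likelihood matches brute force and its limit", {
  tr4 <- ape::read.tree(text = "((a:0.12,b:0.34):0.08,(c:0.2,d:0.05):0.15);")
  aln4 <- tibble::tibble(taxon = c("a", "b", "c", "d"),
                         sequence = c("ACGT", "ACTT", "AAGT", "GCGT"))
  pi <- c(0.3, 0.2, 0.2, 0.3)
  gtr_g <- substitution_model("GTR+G", pi = pi,
                              rates = c(1, 3, 1, 1, 3, 1), alpha = 0.5)
  Q <- build_gtr_q(c(1, 3, 1, 1, 3, 1), pi)
  cats <- discrete_gamma_rates(0.5, 4)
  expect_equal(loglikelihood(tr4, aln4, gtr_g),
               brute_force_loglik_gamma(tr4, aln4, Q, pi, cats),
               tolerance = 1e-9)
  # alpha -> infinity approaches the rate-homogeneous likelihood
  hi <- substitution_model("GTR+G", pi = pi, rates = c(1, 3, 1, 1, 3, 1),
                           alpha = 5000, k = 8)
  flat <- substitution_model("GTR", pi = pi, rates = c(1, 3, 1, 1, 3, 1))
  expect_equal(loglikelihood(tr4, aln4, hi), loglikelihood(tr4, aln4, flat),
               tolerance = 1e-3)
  # discrete gamma category rates average to one
  expect_equal(mean(discrete_gamma_rates(0.3, 4)), 1, tolerance = 1e-12)
  expect_error(loglikelihood(tr4, aln4[0, ], gtr_g))
})

test_that("pruning agrees with an established ML implementation", {
  tr4 <- ape::read.tree(text = "((a:0.12,b:0.34):0.08,(c:0.2,d:0.05):0.15);")
  withr::with_seed(23, {
    aln <- tibble::tibble(taxon = c("a", "b", "c", "d"),
                          sequence = replicate(4, random_seq(200)))
  })
  pi <- c(0.28, 0.22, 0.27, 0.23)
  rates <- c(1.5, 4, 0.8, 1.2, 6, 1)
  mine <- loglikelihood(tr4, aln, substitution_model("GTR", pi = pi,
                                                     rates = rates))
  pd <- phangorn::phyDat(t(sapply(strsplit(aln$sequence, ""), identity)) |>
                           `rownames<-`(aln$taxon))
  fit <- phangorn::pml(tr4, pd, bf = pi, Q = rates)
  expect_equal(mine, fit$logLik, tolerance = 1e-6)
})

test_that("BIC ranking prefers parsimony on identical balanced sequences", {
  aln <- tibble::tibble(taxon = c("a", "b", "c", "d"),
                        sequence = rep(strrep("ACGT", 25), 4))
  tr <- ape::read.tree(text = "((a:0.01,b:0.01):0.01,(c:0.01,d:0.01):0.01);")
  rank <- bic_rank(aln, tr, c("JC", "K2P", "GTR"))
  expect_equal(rank$model[1], "JC")
  # all models reach the same lnL (all-zero branch lengths), so BIC order
  # is parameter count order
  expect_true(max(rank$lnL) - min(rank$lnL) < 1e-3)
  expect_equal(rank$model, c("JC", "K2P", "GTR"))
})

test_that("BIC recovers the generating model on simulated data", {
  tr <- ape::read.tree(text = "((a:0.1,b:0.15):0.05,(c:0.2,d:0.1):0.05);")
  ev <- evolve_alignment(evol_spec(tr, substitution_model("JC"), 8000,
                                   seed = 5))
  r1 <- bic_rank(ev$alignment, tr, c("JC", "GTR"))
  expect_equal(r1$model[1], "JC")
  m <- substitution_model("GTR+G", pi = c(0.4, 0.3, 0.2, 0.1),
                          rates = c(1, 6, 1, 1, 6, 1), alpha = 0.3)
  ev2 <- evolve_alignment(evol_spec(tr, m, 8000, seed = 6))
  r2 <- bic_rank(ev2$alignment, tr, c("JC", "GTR+G"))
  expect_equal(r2$model[1], "GTR+G")
  # convergence is reported honestly per fit; models are ranked either way
  expect_type(r2$converged, "logical")
  expect_true(all(is.finite(r2$bic)))
})
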