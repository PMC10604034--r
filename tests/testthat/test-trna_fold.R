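# independent exhaustive re-scorer over the full template grid
oracle_best_score <- function(seq) {
  b <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n <- length(b)
  score_pair <- function(x, y) {
    k <- paste0(x, y)
    if (k %in% c("AT", "TA", "GC", "CG")) 2L
    else if (k %in% c("GT", "TG")) 1L
    else 0L
  }
  best <- -1L
  for (La in 6:7) for (s1 in 1:2) for (Ld in 3:4) for (ld in 4:9)
    for (s2 in 0:1) for (Lc in 4:5) for (lc in c(5, 7, 9))
      for (Lt in 4:5) for (lt in 4:9) {
        v <- n - (2 * La + s1 + 2 * Ld + ld + s2 + 2 * Lc + lc + 2 * Lt + lt)
        if (v < 3 || v > 23) next
        sc <- 0L
        for (i in 1:La) sc <- sc + score_pair(b[i], b[n + 1 - i])
        d0 <- La + s1 + 1
        for (k in 1:Ld) sc <- sc + score_pair(b[d0 + k - 1],
                                              b[d0 + 2 * Ld + ld - k])
        a0 <- d0 + 2 * Ld + ld + s2
        for (k in 1:Lc) sc <- sc + score_pair(b[a0 + k - 1],
                                              b[a0 + 2 * Lc + lc - k])
        t0 <- a0 + 2 * Lc + lc + v
        for (k in 1:Lt) sc <- sc + score_pair(b[t0 + k - 1],
                                              b[t0 + 2 * Lt + lt - k])
        if (sc > best) best <- sc
      }
  best
}

test_that("a planted 73-nt tRNA with 7/4/5/5 arms is recovered exactly", {
  tr <- simulate_trna(73, "TTC", wobble = 0, seed = 21)
  expect_equal(tr$template$La, 7)
  expect_equal(tr$template$Ld, 4)
  expect_equal(tr$template$Lc, 5)
  expect_equal(tr$template$Lt, 5)
  st <- fold_cloverleaf(tr$seq, anticodon_hint = "TTC")
  expect_equal(unlist(st$template), unlist(tr$template))
  expect_equal(st$pairs$pos5, tr$pairs$pos5)
  expect_equal(st$pairs$pos3, tr$pairs$pos3)
  expect_equal(st$anticodon, "TTC")
  expect_length(st$missing_arms, 0)
  # score maximality against the independent exhaustive enumerator
  expect_equal(st$score, oracle_best_score(tr$seq))
})

test_that("fold score is maximal over the template grid for varied lengths", {
  for (n in c(66, 71, 75)) {
    tr <- simulate_trna(n, "GCA", wobble = 1, seed = n)
    st <- fold_cloverleaf(tr$seq)
    expect_equal(st$score, oracle_best_score(tr$seq))
  }
})

test_that("a DHU-less serine tRNA is flagged with a missing D arm", {
  tr <- simulate_trna(68, "AGC", wobble = 0, dhu_deleted = TRUE, seed = 9)
  st <- fold_cloverleaf(tr$seq, anticodon_hint = "AGC")
  expect_equal(st$missing_arms, "D")
  d_pairs <- dplyr::filter(st$pairs, arm == "D")
  expect_lt(sum(d_pairs$label != "none"), 2)
  # the three real arms are fully paired
  real <- dplyr::filter(st$pairs, arm != "D")
  expect_true(all(real$label != "none"))
})

test_that("planted wobble pairs are labelled wobble, the rest Watson-Crick", {
  tr <- simulate_trna(72, "GTA", wobble = 1, seed = 31)
  st <- fold_cloverleaf(tr$seq, anticodon_hint = "GTA")
  wob <- dplyr::filter(st$pairs, label == "wobble")
  expect_equal(nrow(wob), 1)
  expect_true(paste0(wob$base5, wob$base3) %in% c("GT", "TG"))
  expect_true(all(dplyr::filter(st$pairs, label == "WC")$label == "WC"))
  prof <- pairing_profile(st)
  expect_equal(prof$wobble, 1)
  expect_false(prof$all_wc)
})

test_that("pairing profile counts the pair alphabet correctly", {
  tr <- simulate_trna(70, "ATC", wobble = 0, seed = 4)
  st <- fold_cloverleaf(tr$seq)
  prof <- pairing_profile(st)
  expect_true(prof$all_wc)
  expect_equal(prof$wobble, 0)
  # no legal pair outside {A:T, G:C, G:T}
  legal <- dplyr::filter(st$pairs, label != "none")
  expect_true(all(paste0(legal$base5, legal$base3) %in%
                    c("AT", "TA", "GC", "CG", "GT", "TG")))
})

test_that("double reverse-complement refolds to an identical structure", {
  tr <- simulate_trna(69, "GAC", wobble = 1, seed = 13)
  st1 <- fold_cloverleaf(tr$seq, "GAC")
  st2 <- fold_cloverleaf(revcomp(revcomp(tr$seq)), "GAC")
  expect_equal(st1$pairs, st2$pairs)
  expect_equal(st1$score, st2$score)
})

test_that("fold input validation and failure modes", {
  expect_error(fold_cloverleaf(strrep("A", 40)), "outside 55..95")
  expect_error(fold_cloverleaf(strrep("A", 100)), "outside 55..95")
  # an unpairable homopolymer cannot form an acceptor stem
  expect_error(fold_cloverleaf(strrep("A", 70)), "acceptor stem")
})

test_that("the genome-wide profile reproduces the planted 15/7 wobble split", {
  sim <- default_sim()
  prof <- trna_profile(sim$genome)
  expect_equal(nrow(prof), 22)
  expect_equal(sum(prof$wobble > 0), 15)
  expect_equal(sum(prof$all_wc), 7)
  expect_equal(prof$missing_arms[prof$gene == "trnS1"], "D")
  expect_true(all(prof$missing_arms[prof$gene != "trnS1"] == ""))
  # folded wobble counts equal the realized planted-template counts
  realized <- vapply(sim$truth$trna,
                     function(x) sum(x$pairs$realized == "wobble"), integer(1))
  expect_equal(prof$wobble, unname(realized[prof$gene]))
})

test_that("dot-bracket strings are balanced and match the pair count", {
  tr <- simulate_trna(73, "TTC", wobble = 1, seed = 2)
  st <- fold_cloverleaf(tr$seq, "TTC")
  db <- as_dot_bracket(st)
  expect_equal(nchar(db), st$length)
  n_open <- stringr::str_count(db, "\\(")
  expect_equal(n_open, stringr::str_count(db, "\\)"))
  expect_equal(n_open, sum(st$pairs$label != "none"))
})
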