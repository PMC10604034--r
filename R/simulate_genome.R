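# Synthetic annotated mitogenomes with known ground truth.
#
# The generator emulates a circular teleost mitogenome: 37 genes in the
# canonical order on two strands, per-partition base composition, planted
# junction gaps/overlaps, codon-structured PCGs with configurable
# (in)complete stops, cloverleaf-foldable tRNAs (one optionally DHU-less),
# and a control region carrying a tandem repeat and CSB-like motifs.
# Everything planted is recorded in a ground-truth object for tests.

#' Default per-partition base frequencies
#'
#' Frequencies (A, C, G, T) for each partition, matching the published
#' whole/PCG/rRNA/tRNA/CR compositions of the *Psettodes belcheri*
#' mitogenome shipped in `extdata/psettodes_composition.tsv`.
#'
#' @return Named list of length-4 numeric vectors (A, C, G, T).
#' @export
default_partition_freqs <- function() {
  path <- system.file("extdata", "psettodes_composition.tsv",
                      package = "mitocomp")
  tab <- readr::read_tsv(path, show_col_types = FALSE) |>
    dplyr::filter(.data$accession == "OR231239")
  out <- purrr::map(seq_len(nrow(tab)), function(i) {
    v <- c(A = tab$pct_A[i], C = tab$pct_C[i], G = tab$pct_G[i],
           T = tab$pct_T[i])
    v / sum(v)
  })
  names(out) <- dplyr::recode(tab$partition, CRs = "CR")
  out
}

#' Default feature plan cloned from the published annotation table
#'
#' The 38 features (37 genes + control region) of the *P. belcheri*
#' mitogenome with their printed coordinates, strands, anticodon triplets
#' and codons. Three PCGs whose printed incomplete stops contradict their
#' printed lengths (length mod 3 = 0 admits only a complete 3-mer stop) are
#' planted with complete TAA stops instead; the discrepancy is documented
#' in the package vignette.
#'
#' @return Tibble with `gene`, `ftype`, `start`, `end`, `strand`,
#'   `anticodon`, `start_codon`, `stop_codon`.
#' @export
default_feature_plan <- function() {
  path <- system.file("extdata", "psettodes_belcheri_features.tsv",
                      package = "mitocomp")
  tab <- readr::read_tsv(path, show_col_types = FALSE, na = c("", "NA", "."))
  gene <- normalize_gene_name(tab$gene, tab$anticodon)
  voc <- mito_vocabulary()
  plan <- tibble::tibble(
    gene = gene,
    ftype = voc$ftype[match(gene, voc$gene)],
    start = tab$start, end = tab$end, strand = tab$strand,
    anticodon = tab$anticodon,
    start_codon = tab$start_codon, stop_codon = tab$stop_codon
  )
  # reconcile stop plan with length mod 3 (printed table is inconsistent
  # for ATP6/COIII/ND3)
  plan |>
    dplyr::mutate(
      len = .data$end - .data$start + 1L,
      stop_codon = dplyr::case_when(
        .data$ftype != "PCG" ~ .data$stop_codon,
        !stringr::str_detect(.data$stop_codon, "-") & .data$len %% 3L == 0L ~
          .data$stop_codon,
        .data$len %% 3L == 1L ~ "T--",
        .data$len %% 3L == 2L ~ "TA-",
        TRUE ~ "TAA"
      )
    ) |>
    dplyr::select(-"len")
}

#' Default wobble plan for the 22 tRNAs
#'
#' 15 tRNAs carry one planted G:T wobble pair and 7 are pure Watson-Crick,
#' reproducing the published split; trnS1 is DHU-deleted.
#'
#' @return Tibble with `gene`, `wobble`, `dhu_deleted`.
#' @export
default_wobble_plan <- function() {
  wob <- c("trnA", "trnF", "trnQ", "trnM", "trnW", "trnN", "trnC", "trnY",
           "trnS2", "trnD", "trnG", "trnR", "trnH", "trnE", "trnP")
  tibble::tibble(
    gene = .trna_names,
    wobble = ifelse(.trna_names %in% wob, 1L, 0L),
    dhu_deleted = .trna_names == "trnS1"
  )
}

#' Default control-region plan
#'
#' One 72-bp tandem repeat at 2.5 copies and the four synthetic CSB motifs
#' planted in genome order with zero mismatches, all within a 1023-bp CR.
#'
#' @return List with `repeat_period`, `repeat_copies`, `repeat_offset`
#'   (1-based CR-relative), `csb` (tibble `block`, `motif`, `offset`,
#'   `mismatches`).
#' @export
default_cr_plan <- function() {
  motifs <- csb_motif_library()
  list(
    repeat_period = 72L,
    repeat_copies = 2.5,
    repeat_offset = 150L,
    csb = dplyr::mutate(motifs,
                        offset = c(420L, 470L, 530L, 620L),
                        mismatches = 0L)
  )
}

#' Specify a synthetic mitogenome
#'
#' Validates and bundles the feature plan (either explicit 1-based
#' coordinates, or `length` + `gap_after` columns that must tile the
#' declared circle), per-partition base frequencies, tRNA wobble/DHU plan
#' and control-region plan.
#'
#' @param feature_plan Tibble as in [default_feature_plan()]; alternatively
#'   with `length` and `gap_after` instead of `start`/`end`.
#' @param freqs Named list of A,C,G,T frequency vectors per partition
#'   (whole, PCGs, rRNAs, tRNAs, CR).
#' @param wobble_plan Tibble as in [default_wobble_plan()].
#' @param cr_plan List as in [default_cr_plan()]; `NULL` plants nothing in
#'   the CR (pure i.i.d. composition).
#' @param genome_length Circle length; default max feature end.
#' @param accession Label for the synthetic record.
#' @param seed Integer seed; the whole genome is deterministic under it.
#' @return A `genome_spec` list.
#' @export
genome_spec <- function(feature_plan = default_feature_plan(),
                        freqs = default_partition_freqs(),
                        wobble_plan = default_wobble_plan(),
                        cr_plan = default_cr_plan(),
                        genome_length = NULL,
                        accession = "SYN000001",
                        seed = 42) {
  plan <- tibble::as_tibble(feature_plan)
  if (!"start" %in% names(plan)) {
    # build coordinates from lengths and junction gaps; must tile the circle
    stopifnot(all(c("length", "gap_after") %in% names(plan)))
    start <- integer(nrow(plan))
    end <- integer(nrow(plan))
    pos <- 1L
    for (i in seq_len(nrow(plan))) {
      start[i] <- pos
      end[i] <- pos + plan$length[i] - 1L
      pos <- end[i] + 1L + plan$gap_after[i]
    }
    if (!is.null(genome_length) && pos != genome_length + 1L) {
      stop("spec error: junction plan does not tile the circle at junction ",
           plan$gene[nrow(plan)], " -> ", plan$gene[1],
           " (reached ", pos - 1L, ", declared ", genome_length, ")",
           call. = FALSE)
    }
    if (is.null(genome_length)) genome_length <- pos - 1L
    plan$start <- start
    plan$end <- end
  }
  if (is.null(genome_length)) genome_length <- max(plan$end)
  if (!"ftype" %in% names(plan)) {
    voc <- mito_vocabulary()
    plan$ftype <- voc$ftype[match(plan$gene, voc$gene)]
  }
  if (!"anticodon" %in% names(plan)) plan$anticodon <- NA_character_
  if (!"start_codon" %in% names(plan)) plan$start_codon <- NA_character_
  if (!"stop_codon" %in% names(plan)) plan$stop_codon <- NA_character_

  # codon plan must be consistent with PCG length mod 3
  pcg <- dplyr::filter(plan, .data$ftype == "PCG", !is.na(.data$stop_codon))
  for (i in seq_len(nrow(pcg))) {
    len <- pcg$end[i] - pcg$start[i] + 1L
    stopc <- pcg$stop_codon[i]
    need <- c("0" = 3L, "1" = 1L, "2" = 2L)[[as.character(len %% 3L)]]
    got <- nchar(gsub("-", "", stopc))
    if (got != need) {
      stop("spec error: stop codon '", stopc, "' of ", pcg$gene[i],
           " inconsistent with length ", len, " (mod 3 = ", len %% 3L, ")",
           call. = FALSE)
    }
  }

  # CR plan must fit inside the CR
  cr <- dplyr::filter(plan, .data$ftype == "CR")
  if (!is.null(cr_plan) && nrow(cr) > 0) {
    cr_len <- cr$end[1] - cr$start[1] + 1L
    spans <- list()
    if (!is.null(cr_plan$repeat_period)) {
      rep_len <- ceiling(cr_plan$repeat_period * cr_plan$repeat_copies)
      spans$rep <- c(cr_plan$repeat_offset, cr_plan$repeat_offset + rep_len - 1L)
    }
    if (!is.null(cr_plan$csb)) {
      for (i in seq_len(nrow(cr_plan$csb))) {
        spans[[paste0("csb", i)]] <- c(
          cr_plan$csb$offset[i],
          cr_plan$csb$offset[i] + nchar(cr_plan$csb$motif[i]) - 1L
        )
      }
    }
    for (nm in names(spans)) {
      if (spans[[nm]][1] < 1 || spans[[nm]][2] > cr_len) {
        stop("spec error: CR plant '", nm, "' outside the control region",
             call. = FALSE)
      }
    }
    if (length(spans) > 1) {
      sp <- do.call(rbind, spans)
      sp <- sp[order(sp[, 1]), , drop = FALSE]
      if (any(sp[-1, 1] <= sp[-nrow(sp), 2])) {
        stop("spec error: CR plants overlap each other", call. = FALSE)
      }
    }
  }

  structure(
    list(feature_plan = dplyr::arrange(plan, .data$start), freqs = freqs,
         wobble_plan = wobble_plan, cr_plan = cr_plan,
         genome_length = as.integer(genome_length),
         accession = accession, seed = as.integer(seed)),
    class = "genome_spec"
  )
}

# sample n bases from a frequency vector (A,C,G,T order)
.sample_bases <- function(n, freq) {
  sample(.bases, n, replace = TRUE, prob = freq)
}

#' Build a single cloverleaf-foldable tRNA sequence
#'
#' Generates a tRNA gene of exact length `n` realizing one of the fold
#' templates of [fold_cloverleaf()]: stems are complementary (with the
#' requested number of planted G:T wobble pairs), loops and linkers are
#' drawn from A/C so the planted stems are the unambiguous pairing optimum,
#' and the anticodon triplet sits at the anticodon-loop center. With
#' `dhu_deleted` the whole DHU region is replaced by an unpairable A-run.
#'
#' @param n Length (55-95 nt).
#' @param anticodon 3-mer planted at the loop center.
#' @param wobble Number of planted wobble pairs (0-3).
#' @param dhu_deleted Replace the DHU arm with an unpairable loop.
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @return List: `seq`, `template` (layout parameters), `pairs` (tibble
#'   `arm`, `pos5`, `pos3`, `label` as planted), `wobble`, `dhu_deleted`.
#' @export
simulate_trna <- function(n, anticodon = "TTC", wobble = 0,
                          dhu_deleted = FALSE, seed = NULL) {
  build <- function() {
    grid <- .fold_grid(n)
    if (nrow(grid) == 0) stop("no template for length ", n, call. = FALSE)
    pref <- order(-grid$La, -grid$Lc, -grid$Lt,
                  if (dhu_deleted) grid$Ld else -grid$Ld,
                  abs(grid$lc - 7), abs(grid$ld - 6), abs(grid$lt - 7),
                  grid$v, grid$s1, grid$s2)
    tpl <- as.list(grid[pref[1], ])
    p <- .template_pairs(tpl, n)
    x <- sample(c("A", "C"), n, replace = TRUE, prob = c(0.6, 0.4))
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    arm_keys <- c("acceptor", "d", "anticodon", "t")
    for (arm in arm_keys) {
      pp <- p[[arm]]
      b5 <- sample(.bases, length(pp$pos5), replace = TRUE)
      x[pp$pos5] <- b5
      x[pp$pos3] <- comp[b5]
    }
    # planted wobble pairs: AC-stem pair 2, T-stem pair 2, acceptor pair 3
    slots <- list(c("anticodon", 2L), c("t", 2L), c("acceptor", 3L))
    nw <- min(wobble, length(slots))
    for (i in seq_len(nw)) {
      pp <- p[[slots[[i]][1]]]
      k <- as.integer(slots[[i]][2])
      x[pp$pos5[k]] <- "G"
      x[pp$pos3[k]] <- "T"
    }
    if (dhu_deleted) {
      d_start <- tpl$La + tpl$s1 + 1L
      d_end <- d_start + 2L * tpl$Ld + tpl$ld - 1L
      x[d_start:d_end] <- "A"
    }
    mid <- p$ac_loop[1] + (tpl$lc - 3L) %/% 2L
    x[mid:(mid + 2L)] <- chars(toupper(chartr("U", "T", anticodon)))
    pairs <- purrr::imap_dfr(p[arm_keys], function(pp, key) {
      tibble::tibble(arm = key, pos5 = pp$pos5, pos3 = pp$pos3,
                     label = .pair_label(x[pp$pos5], x[pp$pos3]))
    })
    list(seq = paste(x, collapse = ""), template = tpl, pairs = pairs,
         wobble = nw, dhu_deleted = dhu_deleted)
  }
  # rejection sampling: chance base draws can create an equal-score
  # alternative fold; resample until the planted template is the unique
  # optimum the folder returns
  build_checked <- function() {
    for (attempt in 1:50) {
      tr <- build()
      st <- fold_cloverleaf(tr$seq, anticodon_hint = anticodon)
      tmpl_ok <- if (dhu_deleted) {
        # the D region is unpairable by design, so its allocation is
        # arbitrary; require exact recovery of the three real arms
        fold_real <- dplyr::filter(st$pairs, .data$arm != "D")
        plant_real <- dplyr::filter(tr$pairs, .data$arm != "d")
        identical(fold_real$pos5, plant_real$pos5) &&
          identical(fold_real$pos3, plant_real$pos3)
      } else {
        identical(unlist(st$template), unlist(tr$template))
      }
      ok <- tmpl_ok &&
        sum(st$pairs$label == "wobble") == tr$wobble &&
        identical("D" %in% st$missing_arms, dhu_deleted)
      if (ok) return(tr)
    }
    warning("planted tRNA structure not uniquely recoverable after 50 draws")
    tr
  }
  if (is.null(seed)) build_checked() else with_seed(seed, build_checked())
}

# codon-structured PCG sense sequence: start codon, stop-free interior,
# complete or truncated stop
.simulate_pcg <- function(len, start_codon, stop_codon, freq) {
  stop_tail <- gsub("-", "", stop_codon)
  n_inner <- (len - 3L - nchar(stop_tail)) / 3L
  stopifnot(n_inner == floor(n_inner), n_inner >= 0)
  codons <- apply(expand.grid(.bases, .bases, .bases)[, 3:1], 1, paste,
                  collapse = "")
  pr <- apply(expand.grid(freq, freq, freq)[, 3:1], 1, prod)
  keep <- !(codons %in% .mito_stops)
  inner <- sample(codons[keep], n_inner, replace = TRUE,
                  prob = pr[keep] / sum(pr[keep]))
  paste0(start_codon, paste(inner, collapse = ""), stop_tail)
}

# control region with planted tandem repeat and CSB motifs; returns the
# sequence plus the realized plant records (CR-relative coordinates)
.simulate_cr <- function(len, freq, cr_plan) {
  x <- .sample_bases(len, freq)
  truth <- list(repeats = NULL, csb = NULL)
  if (!is.null(cr_plan)) {
    if (!is.null(cr_plan$repeat_period)) {
      p <- cr_plan$repeat_period
      span <- floor(p * cr_plan$repeat_copies)
      unit <- .sample_bases(p, freq)
      fill <- rep(unit, length.out = span)
      at <- cr_plan$repeat_offset
      x[at:(at + span - 1L)] <- fill
      truth$repeats <- tibble::tibble(
        period = p, copies = span / p, start = at, end = at + span - 1L,
        consensus = paste(unit, collapse = "")
      )
    }
    if (!is.null(cr_plan$csb)) {
      rows <- purrr::map_dfr(seq_len(nrow(cr_plan$csb)), function(i) {
        motif <- chars(toupper(cr_plan$csb$motif[i]))
        mm <- cr_plan$csb$mismatches[i]
        planted <- motif
        if (mm > 0) {
          at_pos <- sample(seq_along(motif), mm)
          for (j in at_pos) {
            planted[j] <- sample(setdiff(.bases, planted[j]), 1)
          }
        }
        off <- cr_plan$csb$offset[i]
        x[off:(off + length(motif) - 1L)] <<- planted
        tibble::tibble(block = cr_plan$csb$block[i], start = off,
                       end = off + length(motif) - 1L, mismatches = mm,
                       identity = (length(motif) - mm) / length(motif))
      })
      truth$csb <- rows
    }
  }
  list(seq = paste(x, collapse = ""), truth = truth)
}

#' Simulate an annotated mitogenome with ground truth
#'
#' Assembles the plus strand of a circular genome from a [genome_spec()]:
#' i.i.d. background (spacers), i.i.d. rRNAs, cloverleaf tRNAs
#' ([simulate_trna()]), codon-structured PCGs and a control region with
#' planted repeat/CSB features. Features are written in annotation order,
#' so in overlap regions the later feature's bases win; a repair pass then
#' restores planted tRNA pairs where one partner position is exclusively
#' owned. Ground truth records both the plan and the *realized* codons and
#' pair labels read back from the final sequence.
#'
#' @param spec A `genome_spec`.
#' @return Object of class `mito_sim`: list with `genome` (a
#'   `mito_genome`) and `truth` (plan, realized codons, tRNA structures and
#'   CR plants).
#' @export
simulate_mitogenome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  plan <- spec$feature_plan
  L <- spec$genome_length
  comp <- c(A = "T", C = "G", G = "C", T = "A")

  out <- with_seed(spec$seed, {
    x <- .sample_bases(L, spec$freqs$whole)
    coverage <- integer(L)
    trna_truth <- list()
    cr_truth <- NULL

    for (i in seq_len(nrow(plan))) {
      f <- plan[i, ]
      len <- f$end - f$start + 1L
      part <- switch(f$ftype, PCG = "PCGs", tRNA = "tRNAs", rRNA = "rRNAs",
                     CR = "CR", "whole")
      sense <- switch(f$ftype,
        rRNA = paste(.sample_bases(len, spec$freqs[[part]]), collapse = ""),
        tRNA = {
          wp <- dplyr::filter(spec$wobble_plan, .data$gene == f$gene)
          tr <- simulate_trna(
            len, anticodon = ifelse(is.na(f$anticodon), "TTC", f$anticodon),
            wobble = if (nrow(wp)) wp$wobble[1] else 0L,
            dhu_deleted = if (nrow(wp)) wp$dhu_deleted[1] else FALSE
          )
          trna_truth[[f$gene]] <- tr
          tr$seq
        },
        PCG = .simulate_pcg(len, f$start_codon, f$stop_codon,
                            spec$freqs[[part]]),
        CR = {
          cr <- .simulate_cr(len, spec$freqs[[part]], spec$cr_plan)
          cr_truth <- cr$truth
          cr$seq
        },
        paste(.sample_bases(len, spec$freqs$whole), collapse = "")
      )
      plus <- if (f$strand == "L") revcomp(sense) else sense
      x[f$start:f$end] <- chars(plus)
      coverage[f$start:f$end] <- coverage[f$start:f$end] + 1L
    }

    # repair planted tRNA pairs broken by a later overlapping feature,
    # wherever one partner position belongs to this tRNA alone
    sense_to_plus <- function(f, s) if (f$strand == "H") f$start + s - 1L
                                    else f$end - s + 1L
    plus_base <- function(f, pp) {
      b <- x[pp]
      if (f$strand == "L") comp[b] else b
    }
    for (g in names(trna_truth)) {
      f <- plan[plan$gene == g, ]
      tr <- trna_truth[[g]]
      for (r in seq_len(nrow(tr$pairs))) {
        p5 <- sense_to_plus(f, tr$pairs$pos5[r])
        p3 <- sense_to_plus(f, tr$pairs$pos3[r])
        b5 <- plus_base(f, p5)
        b3 <- plus_base(f, p3)
        now <- .pair_label(b5, b3)
        want <- tr$pairs$label[r]
        if (now != want && want == "WC") {
          if (coverage[p5] == 1 && coverage[p3] > 1) {
            nb <- comp[b3]
            x[p5] <- if (f$strand == "L") comp[nb] else nb
          } else if (coverage[p3] == 1 && coverage[p5] > 1) {
            nb <- comp[b5]
            x[p3] <- if (f$strand == "L") comp[nb] else nb
          }
        }
      }
      # realized labels after repair
      tr$pairs$realized <- purrr::map_chr(seq_len(nrow(tr$pairs)), function(r) {
        .pair_label(plus_base(f, sense_to_plus(f, tr$pairs$pos5[r])),
                    plus_base(f, sense_to_plus(f, tr$pairs$pos3[r])))
      })
      trna_truth[[g]] <- tr
    }
    list(x = x, trna_truth = trna_truth, cr_truth = cr_truth)
  })

  genome <- mito_genome(
    dplyr::select(plan, "gene", "ftype", "start", "end", "strand",
                  "anticodon"),
    sequence = paste(out$x, collapse = ""),
    accession = spec$accession
  )
  realized <- classify_codons(genome)
  planned <- plan |>
    dplyr::filter(.data$ftype == "PCG") |>
    dplyr::select("gene", planned_start = "start_codon",
                  planned_stop = "stop_codon")
  truth <- list(
    seed = spec$seed,
    feature_plan = plan,
    codons = dplyr::left_join(realized, planned, by = "gene"),
    trna = out$trna_truth,
    cr = out$cr_truth,
    freqs = spec$freqs
  )
  structure(list(genome = genome, truth = truth), class = "mito_sim")
}

#' @export
print.mito_sim <- function(x, ...) {
  cat("<mito_sim> seed ", x$truth$seed, "\n", sep = "")
  print(x$genome)
  invisible(x)
}

#' Write a simulated genome bundle to disk
#'
#' Emits `genome.fasta`, `features.tsv`, `genome.gb` and
#' `ground_truth.json`; the same spec and seed give byte-identical files.
#'
#' @param sim A `mito_sim`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_mitogenome_bundle <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(tibble::tibble(name = sim$genome$accession,
                             sequence = sim$genome$sequence),
              file.path(dir, "genome.fasta"))
  write_feature_table(sim$genome, file.path(dir, "features.tsv"))
  write_genbank(sim$genome, file.path(dir, "genome.gb"))
  truth <- sim$truth
  truth$trna <- purrr::map(truth$trna, function(tr) {
    list(seq = tr$seq, template = tr$template, pairs = tr$pairs,
         wobble = tr$wobble, dhu_deleted = tr$dhu_deleted)
  })
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
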