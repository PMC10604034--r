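# End-to-end characterization and cross-genome comparison.

.try_stage <- function(name, expr, errors_env) {
  tryCatch(expr, error = function(e) {
    errors_env$errors <- dplyr::bind_rows(
      errors_env$errors,
      tibble::tibble(stage = name, message = conditionMessage(e))
    )
    NULL
  })
}

#' Characterize one mitogenome end-to-end
#'
#' Runs the architecture, composition, codon, tRNA-folding and
#' control-region stages on a genome and bundles the results. Stages are
#' fail-soft: stages requiring a sequence are skipped with a recorded
#' message when only a feature table is available, and any stage failure is
#' recorded while the remaining stages still run.
#'
#' @param genome A `mito_genome` (or a path to a feature-table TSV or
#'   GenBank file, dispatched on extension).
#' @param motif_library CSB motifs for the control-region stage.
#' @param include_circular_closure Passed to [architecture_summary()].
#' @return Object of class `mito_report`: list with `summary` (one row),
#'   `architecture`, `junctions`, `partition_lengths`, `partitions`,
#'   `codons`, `trna`, `cr` and `errors` (tibble of skipped/failed stages).
#' @export
characterize <- function(genome, motif_library = csb_motif_library(),
                         include_circular_closure = FALSE) {
  if (is.character(genome)) {
    genome <- if (grepl("\\.(gb|gbk|genbank)$", genome, ignore.case = TRUE)) {
      read_genbank(genome)
    } else {
      read_feature_table(genome)
    }
  }
  env <- new.env()
  env$errors <- tibble::tibble(stage = character(), message = character())

  arch <- .try_stage("architecture",
                     architecture_summary(genome, include_circular_closure),
                     env)
  plens <- .try_stage("partition_lengths", partition_lengths(genome), env)
  has_seq <- !is.null(genome$sequence)
  if (!has_seq) {
    env$errors <- dplyr::bind_rows(env$errors, tibble::tibble(
      stage = c("composition", "codons", "trna", "control_region"),
      message = "skipped: genome has no sequence"
    ))
    warning("no sequence: composition, codon, tRNA and CR stages skipped")
  }
  parts <- if (has_seq) .try_stage("composition", partition_stats(genome), env)
  codons <- if (has_seq) .try_stage("codons", classify_codons(genome), env)
  trna <- if (has_seq) .try_stage("trna", trna_profile(genome), env)
  cr <- if (has_seq) {
    .try_stage("control_region",
               control_region_report(genome, motif_library), env)
  }

  gl <- glance.mito_genome(genome)
  smry <- dplyr::bind_cols(
    gl,
    if (!is.null(arch)) {
      dplyr::select(arch$summary, "n_overlaps", "total_overlap_bp",
                    "n_spacers", "total_spacer_bp", "strand_h", "strand_l")
    }
  )
  structure(
    list(accession = genome$accession, summary = smry,
         architecture = arch,
         junctions = if (!is.null(arch)) arch$junctions,
         partition_lengths = plens, partitions = parts, codons = codons,
         trna = trna, cr = cr, errors = env$errors),
    class = "mito_report"
  )
}

#' @export
print.mito_report <- function(x, ...) {
  s <- x$summary
  cat("<mito_report> ", x$accession, ": ", s$n_genes, " genes (",
      s$n_pcg, " PCGs, ", s$n_trna, " tRNAs, ", s$n_rrna, " rRNAs)",
      if (s$has_cr) " + CR", "\n", sep = "")
  if (nrow(x$errors) > 0) {
    cat("  stages not run:\n")
    for (i in seq_len(nrow(x$errors))) {
      cat("   - ", x$errors$stage[i], ": ", x$errors$message[i], "\n", sep = "")
    }
  }
  invisible(x)
}

#' Write a characterization report bundle
#'
#' TSV per table plus a JSON summary; deterministic given the same report.
#'
#' @param report A `mito_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(tbl, name) {
    if (!is.null(tbl) && nrow(tbl) > 0) {
      readr::write_tsv(tbl, file.path(dir, paste0(name, ".tsv")), na = ".")
    }
  }
  wr(report$junctions, "junctions")
  wr(report$partition_lengths, "partition_lengths")
  wr(report$partitions, "partition_stats")
  wr(report$codons, "codons")
  wr(report$trna, "trna_profile")
  if (!is.null(report$cr)) {
    wr(report$cr$repeats, "cr_repeats")
    wr(report$cr$csb, "cr_csb")
  }
  wr(report$errors, "stage_errors")
  jsonlite::write_json(
    c(list(accession = report$accession), as.list(report$summary)),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE
  )
  invisible(dir)
}

#' Compare two or more mitogenomes
#'
#' Side-by-side architecture summaries, partition statistics (Table-2-shaped
#' partitions x genomes matrix), pairwise gene-order comparisons against the
#' first genome, and (when all genomes carry sequence and an annotated CR)
#' variable sites across each CSB block.
#'
#' @param genomes List of `mito_genome` objects (>= 2).
#' @param motif_library CSB motifs for the cross-genome block comparison.
#' @return Object of class `mito_comparison`: list with `summaries`,
#'   `partition_stats`, `gene_order` (tibble per pair), `csb_variable_sites`.
#' @export
compare_genomes <- function(genomes, motif_library = csb_motif_library()) {
  stopifnot(length(genomes) >= 2)
  accs <- purrr::map_chr(genomes, "accession")
  summaries <- purrr::map_dfr(genomes, function(g) {
    dplyr::bind_cols(glance.mito_genome(g),
                     glance.mito_architecture(architecture_summary(g)) |>
                       dplyr::select("n_overlaps", "total_overlap_bp",
                                     "n_spacers", "total_spacer_bp"))
  })
  has_seq <- purrr::map_lgl(genomes, ~ !is.null(.x$sequence))
  pstats <- if (all(has_seq)) {
    purrr::map2_dfr(genomes, accs, function(g, a) {
      dplyr::mutate(tibble::as_tibble(partition_stats(g)), accession = a,
                    .before = 1)
    })
  }
  go <- purrr::map_dfr(seq_along(genomes)[-1], function(i) {
    cmp <- compare_gene_order(genomes[[1]], genomes[[i]])
    tibble::tibble(
      a = accs[1], b = accs[i], identical = cmp$identical,
      breakpoint_distance = cmp$breakpoint_distance,
      differing = paste(
        paste(cmp$differing_adjacencies$from, cmp$differing_adjacencies$to,
              sep = "->"), collapse = "; "),
      missing_genes = paste(cmp$missing_genes$gene, collapse = ";")
    )
  })
  csb_var <- NULL
  if (all(has_seq)) {
    csb_var <- tryCatch({
      hits <- purrr::map(genomes, function(g) {
        cr <- dplyr::filter(g$features, .data$ftype == "CR")
        cr_seq <- extract_feature_sequence(g, cr[1, ])
        list(seq = cr_seq, hits = scan_csb(cr_seq, motif_library))
      })
      purrr::map_dfr(motif_library$block, function(bl) {
        segs <- purrr::map_chr(hits, function(h) {
          row <- dplyr::filter(h$hits, .data$block == bl, .data$found)
          if (nrow(row) == 0) return(NA_character_)
          substr(h$seq, row$start[1], row$end[1])
        })
        if (anyNA(segs)) {
          return(tibble::tibble(block = bl, n_variable = NA_integer_,
                                n_parsimony_informative = NA_integer_))
        }
        vs <- variable_sites(segs)
        tibble::tibble(block = bl, n_variable = length(vs$variable),
                       n_parsimony_informative =
                         length(vs$parsimony_informative))
      })
    }, error = function(e) NULL)
  }
  structure(
    list(accessions = accs, summaries = summaries, partition_stats = pstats,
         gene_order = go, csb_variable_sites = csb_var),
    class = "mito_comparison"
  )
}

#' @export
print.mito_comparison <- function(x, ...) {
  cat("<mito_comparison> ", paste(x$accessions, collapse = " vs "), "\n",
      sep = "")
  print(x$summaries)
  invisible(x)
}
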