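# External representations: feature-table TSV, FASTA, GenBank flat files.
# Coordinates are 1-based inclusive everywhere in I/O.

#' Read an annotation feature table (TSV)
#'
#' Reads a Table-1-style TSV with columns `gene`, `start`, `end`, `strand`
#' and optionally `anticodon`, `ftype`, `size`. Gene labels are normalized to
#' the controlled vocabulary ([normalize_gene_name()]); feature types are
#' inferred from the vocabulary when no `ftype` column is present. Sizes are
#' recomputed as `end - start + 1`; if the file carries a `size` column,
#' mismatches are reported as warnings, never errors.
#'
#' @param path TSV file path.
#' @param genome_length Total genome length in bp; defaults to the maximum
#'   feature end.
#' @param accession Identifier for the resulting genome.
#' @return A `mito_genome` without sequence.
#' @export
read_feature_table <- function(path, genome_length = NULL,
                               accession = basename(path)) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         na = c("", "NA", "."), comment = "#")
  feature_table_to_genome(tab, genome_length = genome_length,
                          accession = accession)
}

#' Build a mito_genome from an in-memory feature table
#'
#' Same contract as [read_feature_table()] but starting from a data frame.
#'
#' @param tab Data frame with columns `gene`, `start`, `end`, `strand`, and
#'   optionally `anticodon`, `ftype`, `size`.
#' @inheritParams read_feature_table
#' @return A `mito_genome` without sequence.
#' @export
feature_table_to_genome <- function(tab, genome_length = NULL,
                                    accession = "feature_table") {
  tab <- tibble::as_tibble(tab)
  required <- c("gene", "start", "end", "strand")
  miss <- setdiff(required, names(tab))
  if (length(miss) > 0) {
    stop("feature table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(tab$start > tab$end)) {
    stop("coordinate error: start > end in row ",
         which(tab$start > tab$end)[1], call. = FALSE)
  }
  ac <- if ("anticodon" %in% names(tab)) as.character(tab$anticodon)
        else rep(NA_character_, nrow(tab))
  gene <- normalize_gene_name(tab$gene, ac)
  voc <- mito_vocabulary()
  ftype <- if ("ftype" %in% names(tab)) as.character(tab$ftype) else {
    voc$ftype[match(gene, voc$gene)]
  }
  ftype[is.na(ftype)] <- "other"
  if ("size" %in% names(tab)) {
    recomputed <- tab$end - tab$start + 1
    off <- which(!is.na(tab$size) & tab$size != recomputed)
    if (length(off) > 0) {
      warning("size column disagrees with end - start + 1 for: ",
              paste(gene[off], collapse = ", "))
    }
  }
  feats <- tibble::tibble(gene = gene, ftype = ftype,
                          start = tab$start, end = tab$end,
                          strand = as.character(tab$strand), anticodon = ac)
  mito_genome(feats, sequence = NULL, genome_length = genome_length,
              accession = accession)
}

#' Write a feature table TSV
#'
#' Emits columns `gene, ftype, start, end, strand, anticodon, size`; a
#' round-trip through [read_feature_table()] reproduces the genome.
#'
#' @param genome A `mito_genome`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(genome, path) {
  tab <- genome$features |>
    dplyr::mutate(size = .data$end - .data$start + 1L) |>
    dplyr::select("gene", "ftype", "start", "end", "strand", "anticodon",
                  "size")
  readr::write_tsv(tab, path, na = ".")
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return A tibble with columns `name` and `sequence` (upper case).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble::tibble(name = names(x),
                 sequence = unname(toupper(as.character(x))))
}

#' Write sequences to a FASTA file
#'
#' @param seqs A tibble/data frame with columns `name` and `sequence`, or a
#'   named character vector.
#' @param path Output path.
#' @param width Line width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  if (is.character(seqs)) {
    seqs <- tibble::tibble(name = names(seqs), sequence = unname(seqs))
  }
  x <- Biostrings::DNAStringSet(seqs$sequence)
  names(x) <- seqs$name
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

# ---- GenBank flat files -----------------------------------------------------
# Minimal parser for the subset used by mitogenome records: LOCUS, FEATURES
# with gene/CDS/tRNA/rRNA/D-loop keys, and ORIGIN.

#' Read a GenBank flat file into a mito_genome
#'
#' Parses LOCUS (length), the FEATURES table (`CDS`, `tRNA`, `rRNA`,
#' `D-loop`; `complement(a..b)` marks the light strand) and ORIGIN. Gene
#' labels from `/gene=` or `/product=` qualifiers are normalized to the
#' controlled vocabulary; unknown feature keys are retained with
#' `ftype = "other"`.
#'
#' @param path GenBank flat file.
#' @return A `mito_genome` with sequence (if ORIGIN present) and features.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus_i <- which(stringr::str_detect(lines, "^LOCUS"))
  if (length(locus_i) != 1) {
    stop("parse error: expected exactly one LOCUS line (line ",
         if (length(locus_i)) locus_i[1] else NA, ")", call. = FALSE)
  }
  locus <- stringr::str_match(lines[locus_i],
                              "^LOCUS\\s+(\\S+)\\s+(\\d+)\\s+bp")
  if (is.na(locus[1, 1])) {
    stop("parse error: malformed LOCUS at line ", locus_i, call. = FALSE)
  }
  accession <- locus[1, 2]
  declared_len <- as.integer(locus[1, 3])

  feat_i <- which(stringr::str_detect(lines, "^FEATURES"))
  origin_i <- which(stringr::str_detect(lines, "^ORIGIN"))
  end_i <- which(stringr::str_detect(lines, "^//"))
  stop_feat <- min(c(origin_i, end_i, length(lines) + 1L))

  feats <- tibble::tibble(gene = character(), ftype = character(),
                          start = integer(), end = integer(),
                          strand = character(), anticodon = character())
  if (length(feat_i) == 1) {
    block <- lines[(feat_i + 1):(stop_feat - 1)]
    # a new feature starts at indent 5 with a key; qualifiers are deeper
    starts <- which(stringr::str_detect(block, "^ {5}\\S"))
    key_map <- c(CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA", "D-loop" = "CR")
    for (k in seq_along(starts)) {
      a <- starts[k]
      b <- if (k < length(starts)) starts[k + 1] - 1 else length(block)
      head_m <- stringr::str_match(block[a], "^ {5}(\\S+)\\s+(\\S+)")
      key <- head_m[1, 2]
      loc <- head_m[1, 3]
      if (is.na(key) || is.na(loc)) {
        stop("parse error: malformed feature at FEATURES line ", a,
             call. = FALSE)
      }
      if (key %in% c("source", "gene")) next  # gene keys duplicate CDS/tRNA spans
      strand <- if (stringr::str_detect(loc, "^complement\\(")) "L" else "H"
      nums <- stringr::str_match(loc, "(\\d+)\\.\\.[<>]?(\\d+)")
      if (is.na(nums[1, 1])) {
        stop("parse error: cannot parse location '", loc,
             "' at FEATURES line ", a, call. = FALSE)
      }
      qual <- paste(block[a:b], collapse = " ")
      gene_q <- stringr::str_match(qual, "/gene=\"([^\"]+)\"")[1, 2]
      prod_q <- stringr::str_match(qual, "/product=\"([^\"]+)\"")[1, 2]
      note_ac <- stringr::str_match(qual, "/anticodon_seq=\"([A-Za-z]{3})\"")[1, 2]
      label <- if (!is.na(gene_q)) gene_q else prod_q
      if (is.na(label)) label <- key
      ftype <- if (key %in% names(key_map)) key_map[[key]] else "other"
      feats <- dplyr::bind_rows(feats, tibble::tibble(
        gene = label, ftype = ftype,
        start = as.integer(nums[1, 2]), end = as.integer(nums[1, 3]),
        strand = strand, anticodon = note_ac
      ))
    }
  }

  sequence <- NULL
  if (length(origin_i) == 1) {
    seq_lines <- lines[(origin_i + 1):(min(end_i, length(lines) + 1L) - 1)]
    sequence <- toupper(paste(stringr::str_remove_all(seq_lines, "[ 0-9/]"),
                              collapse = ""))
    if (nchar(sequence) == 0) sequence <- NULL
  }

  if (nrow(feats) > 0) {
    feats$gene <- suppressWarnings(
      normalize_gene_name(feats$gene, feats$anticodon))
    if (any(feats$end > declared_len)) {
      bad <- feats$gene[feats$end > declared_len][1]
      stop("coordinate error: feature '", bad,
           "' exceeds declared sequence length ", declared_len, call. = FALSE)
    }
  }
  mito_genome(feats, sequence = sequence, genome_length = declared_len,
              accession = accession)
}

#' Write a mito_genome as a GenBank flat file
#'
#' Companion writer for [read_genbank()] (round-trip oracle and export of
#' simulated genomes). Emits LOCUS, FEATURES (CDS/tRNA/rRNA/D-loop) and
#' ORIGIN when a sequence is present.
#'
#' @param genome A `mito_genome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, path) {
  key_of <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA", CR = "D-loop",
              other = "misc_feature")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     circular     %s",
                     genome$accession, genome$genome_length,
                     "UNA"), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", genome$genome_length), con)
  for (i in seq_len(nrow(genome$features))) {
    f <- genome$features[i, ]
    loc <- sprintf("%d..%d", f$start, f$end)
    if (f$strand == "L") loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     %-15s %s", key_of[[f$ftype]], loc), con)
    writeLines(sprintf("                     /gene=\"%s\"", f$gene), con)
    if (!is.na(f$anticodon) && nzchar(f$anticodon)) {
      writeLines(sprintf("                     /anticodon_seq=\"%s\"",
                         f$anticodon), con)
    }
  }
  if (!is.null(genome$sequence)) {
    writeLines("ORIGIN", con)
    s <- tolower(genome$sequence)
    pos <- seq(1, nchar(s), by = 60)
    for (p in pos) {
      chunk <- substr(s, p, min(p + 59, nchar(s)))
      groups <- substring(chunk, seq(1, nchar(chunk), 10),
                          pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
      writeLines(sprintf("%9d %s", p, paste(groups, collapse = " ")), con)
    }
  }
  writeLines("//", con)
  invisible(path)
}
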