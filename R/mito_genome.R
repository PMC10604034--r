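# The MitoGenome container: circular sequence + ordered feature annotations.

#' Construct a mitochondrial genome object
#'
#' Bundles an (optional) circular nucleotide sequence with an ordered feature
#' annotation table. Every analysis stage of the package consumes this object.
#'
#' @param features A data frame with columns `gene`, `ftype` (one of PCG,
#'   tRNA, rRNA, CR), `start`, `end` (1-based inclusive, `end >= start`),
#'   `strand` ("H" or "L") and optionally `anticodon` (3-mer, tRNAs only).
#' @param sequence Optional single nucleotide string over A,C,G,T,N. May be
#'   `NULL` when only a feature table is available.
#' @param genome_length Total length in bp; defaults to `nchar(sequence)`
#'   when a sequence is given, otherwise to the maximum feature `end`.
#' @param accession Identifier string.
#' @return An object of class `mito_genome`: a list with elements
#'   `accession`, `sequence`, `genome_length` and `features` (a tibble
#'   sorted by `start`).
#' @export
#' @examples
#' g <- mito_genome(
#'   tibble::tibble(gene = "CR", ftype = "CR", start = 1, end = 10,
#'                  strand = "H", anticodon = NA),
#'   sequence = "ACGTACGTAC"
#' )
#' g
mito_genome <- function(features, sequence = NULL, genome_length = NULL,
                        accession = "unknown") {
  features <- tibble::as_tibble(features)
  required <- c("gene", "ftype", "start", "end", "strand")
  missing_cols <- setdiff(required, names(features))
  if (length(missing_cols) > 0) {
    stop("features is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"anticodon" %in% names(features)) features$anticodon <- NA_character_
  features <- features |>
    dplyr::mutate(
      start = as.integer(.data$start),
      end = as.integer(.data$end),
      anticodon = as.character(.data$anticodon)
    ) |>
    dplyr::select("gene", "ftype", "start", "end", "strand", "anticodon",
                  dplyr::everything())

  if (!is.null(sequence)) {
    stopifnot(length(sequence) == 1)
    sequence <- toupper(sequence)
    assert_nucleotides(sequence, allow_n = TRUE, what = "genome sequence")
    if (is.null(genome_length)) genome_length <- nchar(sequence)
    if (genome_length != nchar(sequence)) {
      stop("genome_length (", genome_length, ") != sequence length (",
           nchar(sequence), ")", call. = FALSE)
    }
  }
  if (is.null(genome_length)) {
    genome_length <- if (nrow(features) > 0) max(features$end) else 0L
  }
  genome_length <- as.integer(genome_length)

  g <- structure(
    list(accession = accession, sequence = sequence,
         genome_length = genome_length,
         features = dplyr::arrange(features, .data$start)),
    class = "mito_genome"
  )
  validate_mito_genome(g)
  g
}

#' Validate a mito_genome object
#'
#' Checks coordinate sanity (`end >= start`, features within the genome),
#' feature types, strand labels, the anticodon-iff-tRNA rule, and gene-name
#' uniqueness.
#'
#' @param g A `mito_genome`.
#' @return `g`, invisibly; errors describe the first violated invariant.
#' @export
validate_mito_genome <- function(g) {
  f <- g$features
  if (nrow(f) == 0) return(invisible(g))
  if (any(f$end < f$start)) {
    bad <- f$gene[f$end < f$start][1]
    stop("coordinate error: start > end for feature '", bad, "'", call. = FALSE)
  }
  if (any(f$end > g$genome_length)) {
    bad <- f$gene[f$end > g$genome_length][1]
    stop("coordinate error: feature '", bad, "' exceeds genome length ",
         g$genome_length, call. = FALSE)
  }
  if (!all(f$ftype %in% c("PCG", "tRNA", "rRNA", "CR", "other"))) {
    stop("ftype must be one of PCG, tRNA, rRNA, CR, other", call. = FALSE)
  }
  if (!all(f$strand %in% c("H", "L"))) {
    stop("strand must be 'H' or 'L'", call. = FALSE)
  }
  has_ac <- !is.na(f$anticodon) & f$anticodon != "" & f$anticodon != "."
  if (any(has_ac & f$ftype != "tRNA")) {
    stop("anticodon present on a non-tRNA feature", call. = FALSE)
  }
  dup <- f$gene[duplicated(f$gene)]
  if (length(dup) > 0) {
    stop("validation error: duplicate gene name(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  invisible(g)
}

#' @export
print.mito_genome <- function(x, ...) {
  cat("<mito_genome> ", x$accession, ": ", x$genome_length, " bp, ",
      nrow(x$features), " features",
      if (is.null(x$sequence)) " (no sequence)" else "", "\n", sep = "")
  print(x$features, n = 6)
  invisible(x)
}

#' Tidy a mito_genome into its feature table
#'
#' @param x A `mito_genome`.
#' @param ... Unused.
#' @return The feature tibble with a computed `size` column (bp).
#' @export
tidy.mito_genome <- function(x, ...) {
  dplyr::mutate(x$features, size = .data$end - .data$start + 1L)
}

#' One-row summary of a mito_genome
#'
#' @param x A `mito_genome`.
#' @param ... Unused.
#' @return Tibble with accession, genome length, feature counts by type and
#'   presence of sequence.
#' @export
glance.mito_genome <- function(x, ...) {
  f <- x$features
  tibble::tibble(
    accession = x$accession,
    genome_length = x$genome_length,
    n_features = nrow(f),
    n_genes = sum(f$ftype %in% c("PCG", "tRNA", "rRNA")),
    n_pcg = sum(f$ftype == "PCG"),
    n_trna = sum(f$ftype == "tRNA"),
    n_rrna = sum(f$ftype == "rRNA"),
    has_cr = any(f$ftype == "CR"),
    has_sequence = !is.null(x$sequence)
  )
}

#' Extract the sense-strand sequence of a feature
#'
#' Returns the substring of the genome covered by the feature: the plus
#' (heavy) strand substring for strand "H", its reverse complement for
#' strand "L". For circular genomes an origin-spanning feature may be
#' requested by passing `end < start` (internal convention); extraction then
#' wraps through position 1.
#'
#' @param genome A `mito_genome` with a sequence.
#' @param feature Either a gene name present in the genome, or a one-row data
#'   frame/list with `start`, `end`, `strand`.
#' @return A single nucleotide string (sense strand).
#' @export
#' @examples
#' g <- mito_genome(tibble::tibble(gene = "x", ftype = "other", start = 1,
#'                                 end = 3, strand = "L", anticodon = NA),
#'                  sequence = "ATGCCC")
#' extract_feature_sequence(g, "x")  # "CAT"
extract_feature_sequence <- function(genome, feature) {
  if (is.null(genome$sequence)) {
    stop("state error: genome has no sequence to extract from", call. = FALSE)
  }
  if (is.character(feature) && length(feature) == 1) {
    row <- dplyr::filter(genome$features, .data$gene == feature)
    if (nrow(row) == 0) stop("no feature named '", feature, "'", call. = FALSE)
    feature <- row[1, ]
  }
  s <- feature$start
  e <- feature$end
  n <- genome$genome_length
  if (s < 1 || e < 1 || s > n || e > n) {
    stop("coordinate error: feature outside genome", call. = FALSE)
  }
  seq <- if (e >= s) {
    substr(genome$sequence, s, e)
  } else {
    # circular wrap through the origin
    paste0(substr(genome$sequence, s, n), substr(genome$sequence, 1, e))
  }
  if (identical(feature$strand, "L")) revcomp(seq) else seq
}
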