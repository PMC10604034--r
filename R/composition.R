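# Nucleotide composition, AT/GC skews, start/stop codon classification.

#' Base composition of a nucleotide sequence
#'
#' Counts A/C/G/T (N's excluded from the denominator) and reports
#' percentages rounded half-up to 2 decimals, plus AT/GC skews rounded to 3.
#' Raw counts are retained unrounded.
#'
#' @param seq A single nucleotide string.
#' @return One-row tibble: `length`, `n_A`, `n_C`, `n_G`, `n_T`, `n_N`,
#'   `pct_A`, `pct_T`, `pct_G`, `pct_C`, `pct_AT`, `at_skew`, `gc_skew`.
#' @export
#' @examples
#' base_composition("AATT")
base_composition <- function(seq) {
  stopifnot(length(seq) == 1)
  if (is.na(seq) || nchar(seq) == 0) {
    stop("value error: empty sequence", call. = FALSE)
  }
  seq <- toupper(seq)
  assert_nucleotides(seq)
  n <- c(A = stringr::str_count(seq, stringr::fixed("A")),
         C = stringr::str_count(seq, stringr::fixed("C")),
         G = stringr::str_count(seq, stringr::fixed("G")),
         T = stringr::str_count(seq, stringr::fixed("T")),
         N = stringr::str_count(seq, stringr::fixed("N")))
  denom <- sum(n[c("A", "C", "G", "T")])
  if (denom == 0) stop("value error: no unambiguous bases", call. = FALSE)
  pct <- 100 * n[c("A", "T", "G", "C")] / denom
  sk <- skews(n[["A"]], n[["T"]], n[["G"]], n[["C"]])
  tibble::tibble(
    length = nchar(seq),
    n_A = n[["A"]], n_C = n[["C"]], n_G = n[["G"]], n_T = n[["T"]],
    n_N = n[["N"]],
    pct_A = round_half_up(pct[["A"]], 2), pct_T = round_half_up(pct[["T"]], 2),
    pct_G = round_half_up(pct[["G"]], 2), pct_C = round_half_up(pct[["C"]], 2),
    pct_AT = round_half_up(pct[["A"]] + pct[["T"]], 2),
    at_skew = sk$at_skew, gc_skew = sk$gc_skew
  )
}

#' AT and GC skew
#'
#' Strand-asymmetry statistics `AT-skew = (A - T)/(A + T)` and
#' `GC-skew = (G - C)/(G + C)`. Scale-invariant: counts and percentages give
#' the same value. Values are rounded half-up at the reporting boundary
#' (3 decimals by default); pass `digits = NULL` for unrounded values.
#'
#' @param a,t,g,c Counts or percentages of the four bases.
#' @param digits Reporting precision (default 3); `NULL` for no rounding.
#' @return A list with `at_skew` and `gc_skew`. When `A + T == 0` (or
#'   `G + C == 0`) the corresponding skew is `NA` (undefined, not 0).
#' @export
#' @examples
#' skews(28.09, 26.06, 16.24, 29.56)  # 0.037, -0.291
skews <- function(a, t, g, c, digits = 3) {
  if (any(c(a, t, g, c) < 0)) stop("value error: negative counts", call. = FALSE)
  at <- if (a + t > 0) (a - t) / (a + t) else NA_real_
  gc <- if (g + c > 0) (g - c) / (g + c) else NA_real_
  if (!is.null(digits)) {
    at <- round_half_up(at, digits)
    gc <- round_half_up(gc, digits)
  }
  list(at_skew = at, gc_skew = gc)
}

#' Partition-wise composition statistics
#'
#' Computes composition and skews for the whole genome and for the PCG,
#' rRNA, tRNA and control-region partitions. A partition's sequence is the
#' concatenation of its member features in annotation order, taken on the
#' deposited heavy (plus) strand: light-strand genes contribute their
#' plus-strand substring, matching whole-sequence per-genome statistics
#' (codon analysis alone uses sense strands). Partitions with no members are
#' omitted with a warning.
#'
#' @param genome A `mito_genome` with sequence.
#' @return A tibble of class `mito_partition_stats`: one row per partition
#'   with `partition`, `length`, percentage and skew columns.
#' @export
partition_stats <- function(genome) {
  if (is.null(genome$sequence)) {
    stop("state error: partition_stats requires a sequence", call. = FALSE)
  }
  members <- list(
    whole = NULL,
    PCGs = dplyr::filter(genome$features, .data$ftype == "PCG"),
    rRNAs = dplyr::filter(genome$features, .data$ftype == "rRNA"),
    tRNAs = dplyr::filter(genome$features, .data$ftype == "tRNA"),
    CR = dplyr::filter(genome$features, .data$ftype == "CR")
  )
  rows <- purrr::imap(members, function(f, part) {
    seq <- if (part == "whole") {
      genome$sequence
    } else {
      if (nrow(f) == 0) {
        warning("partition '", part, "' has no members; omitted")
        return(NULL)
      }
      paste(purrr::map_chr(seq_len(nrow(f)), function(i) {
        substr(genome$sequence, f$start[i], f$end[i])  # plus strand
      }), collapse = "")
    }
    dplyr::bind_cols(tibble::tibble(partition = part), base_composition(seq))
  })
  out <- dplyr::bind_rows(purrr::compact(rows))
  class(out) <- c("mito_partition_stats", class(out))
  out
}

#' Partition lengths from annotations alone
#'
#' Length accounting that needs no sequence: total bp per partition computed
#' from the feature coordinates (whole = genome length).
#'
#' @param genome A `mito_genome`.
#' @return Tibble with `partition`, `n_features`, `length`.
#' @export
partition_lengths <- function(genome) {
  f <- genome$features |>
    dplyr::mutate(size = .data$end - .data$start + 1L,
                  partition = dplyr::recode(.data$ftype, PCG = "PCGs",
                                            tRNA = "tRNAs", rRNA = "rRNAs"))
  by_part <- f |>
    dplyr::group_by(.data$partition) |>
    dplyr::summarise(n_features = dplyr::n(), length = sum(.data$size),
                     .groups = "drop")
  dplyr::bind_rows(
    tibble::tibble(partition = "whole", n_features = nrow(f),
                   length = genome$genome_length),
    by_part
  )
}

# vertebrate mitochondrial stop codons (translation table 2)
.mito_stops <- c("TAA", "TAG", "AGA", "AGG")

#' Classify start and stop codons of protein-coding genes
#'
#' Extracts each PCG's sense-strand sequence and reports the first 3-mer as
#' the start codon and a stop classified from `length mod 3`: remainder 0
#' gives the final 3-mer (complete), remainder 1 the final base plus `"--"`,
#' remainder 2 the final two bases plus `"-"` (both incomplete; completed to
#' TAA by post-transcriptional polyadenylation in vivo).
#'
#' @param genome A `mito_genome` with sequence.
#' @return A tibble with `gene`, `length`, `start_codon`, `stop_codon`,
#'   `stop_class` ("complete"/"incomplete").
#' @export
classify_codons <- function(genome) {
  if (is.null(genome$sequence)) {
    stop("state error: classify_codons requires a sequence", call. = FALSE)
  }
  pcg <- dplyr::filter(genome$features, .data$ftype == "PCG")
  purrr::map_dfr(seq_len(nrow(pcg)), function(i) {
    f <- pcg[i, ]
    s <- extract_feature_sequence(genome, f)
    len <- nchar(s)
    if (len < 6) {
      stop("validation error: PCG '", f$gene, "' shorter than 6 nt",
           call. = FALSE)
    }
    r <- len %% 3
    stop_codon <- switch(as.character(r),
      "0" = substr(s, len - 2, len),
      "1" = paste0(substr(s, len, len), "--"),
      "2" = paste0(substr(s, len - 1, len), "-")
    )
    tibble::tibble(
      gene = f$gene, length = len,
      start_codon = substr(s, 1, 3),
      stop_codon = stop_codon,
      stop_class = ifelse(grepl("-", stop_codon), "incomplete", "complete")
    )
  })
}
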