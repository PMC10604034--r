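# Control-region analytics: tandem repeats, CSB motif scanning, variable sites.

#' Find tandem repeats by deterministic period scan
#'
#' For each candidate period `p` the sequence is compared against itself at
#' lag `p`; maximal runs whose self-match identity stays at or above
#' `min_identity` are extended greedily, a period-length consensus is built
#' by column majority, and records passing the copy-number and identity
#' thresholds are emitted. Overlapping reports of the same locus are
#' collapsed to the highest-identity, smallest-period record. This is a
#' reproducible, exhaustively checkable scanner, not a probabilistic
#' aligner; it is intended for control-region scale (~1 kb).
#'
#' @param seq Nucleotide string.
#' @param min_period,max_period Period bounds (bp); must satisfy
#'   `1 <= min_period <= max_period <= nchar(seq)/2`.
#' @param min_copies Minimum (possibly fractional) copy number (default 2).
#' @param min_identity Minimum fraction of positions matching the consensus
#'   (default 0.9).
#' @return Tibble with `period`, `copies`, `start`, `end`, `consensus`,
#'   `identity`; zero rows when nothing passes.
#' @export
#' @examples
#' find_tandem_repeats("ACGTACGTACGT", 2, 6)
find_tandem_repeats <- function(seq, min_period, max_period,
                                min_copies = 2, min_identity = 0.9) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (min_period < 1 || min_period > max_period || max_period > n / 2) {
    stop("value error: need 1 <= min_period <= max_period <= length/2",
         call. = FALSE)
  }
  if (min_copies < 1 || min_identity <= 0 || min_identity > 1) {
    stop("value error: invalid min_copies/min_identity", call. = FALSE)
  }
  b <- chars(seq)
  records <- list()
  for (p in min_period:max_period) {
    m <- b[seq_len(n - p)] == b[(p + 1):n]
    # runs of self-matches at lag p, merged while identity holds
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    true_runs <- which(r$values)
    if (length(true_runs) == 0) next
    i <- 1
    while (i <= length(true_runs)) {
      a <- starts[true_runs[i]]
      e <- ends[true_runs[i]]
      j <- i
      while (j < length(true_runs)) {
        e2 <- ends[true_runs[j + 1]]
        ident <- sum(m[a:e2]) / (e2 - a + 1)
        if (ident >= min_identity) { e <- e2; j <- j + 1 } else break
      }
      raw_copies <- (e + p - a + 1) / p
      if (raw_copies >= min_copies) {
        trimmed <- .trim_repeat_span(b, a, e + p, p)
        copies <- (trimmed$end - trimmed$start + 1) / p
        if (copies >= min_copies && trimmed$identity >= min_identity) {
          records[[length(records) + 1]] <- tibble::tibble(
            period = p, copies = copies,
            start = trimmed$start, end = trimmed$end,
            consensus = trimmed$consensus, identity = trimmed$identity
          )
        }
      }
      i <- j + 1
    }
  }
  if (length(records) == 0) {
    return(tibble::tibble(period = integer(), copies = double(),
                          start = integer(), end = integer(),
                          consensus = character(), identity = double()))
  }
  out <- dplyr::bind_rows(records)
  .collapse_repeat_records(out)
}

# chance lag-matches flanking a true repeat can be absorbed by the greedy
# merge; shrink each boundary (up to one period) to the trim maximizing
# consensus identity, preferring the longest span on ties
.trim_repeat_span <- function(b, start, end, p) {
  best <- NULL
  for (tl in 0:min(p, end - start - 2 * p + 1)) {
    for (tr in 0:min(p, end - start - 2 * p + 1 - tl)) {
      s <- start + tl
      e <- end - tr
      if (e - s + 1 < 2 * p) next
      cons <- .repeat_consensus(b, s, e, p)
      better <- is.null(best) ||
        cons$identity > best$identity + 1e-12 ||
        (abs(cons$identity - best$identity) <= 1e-12 &&
           (e - s) > (best$end - best$start))
      if (better) {
        best <- list(start = s, end = e, identity = cons$identity,
                     consensus = cons$consensus)
      }
    }
  }
  if (is.null(best)) {
    cons <- .repeat_consensus(b, start, end, p)
    best <- list(start = start, end = end, identity = cons$identity,
                 consensus = cons$consensus)
  }
  best
}

.repeat_consensus <- function(b, start, end, p) {
  span <- b[start:end]
  col <- ((seq_along(span) - 1L) %% p) + 1L
  cons <- vapply(seq_len(p), function(j) {
    tab <- table(span[col == j])
    names(tab)[which.max(tab)]
  }, character(1))
  identity <- mean(span == cons[col])
  list(consensus = paste(cons, collapse = ""), identity = identity)
}

# keep the best record per overlapping locus: highest identity, then
# smallest period, then longest span
.collapse_repeat_records <- function(recs) {
  recs <- recs[order(-recs$identity, recs$period, -(recs$end - recs$start)), ]
  kept <- recs[0, ]
  for (i in seq_len(nrow(recs))) {
    r <- recs[i, ]
    overlaps <- nrow(kept) > 0 &&
      any(r$start <= kept$end & r$end >= kept$start)
    if (!overlaps) kept <- dplyr::bind_rows(kept, r)
  }
  dplyr::arrange(kept, .data$start)
}

#' Default conserved-sequence-block motif library
#'
#' Synthetic consensus motifs for CSB-D, CSB-I, CSB-II and CSB-III with the
#' block lengths typical of teleost control regions (27/36/51/35 bp). The
#' library is an editable configuration: results on real data depend
#' entirely on the motifs supplied, and these defaults are package-invented
#' stand-ins, not published consensus sequences.
#'
#' @param path Optional FASTA file of named motifs overriding the default.
#' @return Tibble with `block` and `motif`.
#' @export
csb_motif_library <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "csb_motifs_synthetic.fa",
                        package = "mitocomp")
  }
  fa <- read_fasta(path)
  tibble::tibble(block = fa$name, motif = fa$sequence)
}

#' Scan a control region for conserved sequence blocks
#'
#' Best local ungapped alignment of each motif (match +1, mismatch -1)
#' against the control-region sequence. A block is reported found when the
#' best score reaches `score_fraction * motif length`; blocks below the
#' threshold are reported absent with `found = FALSE`.
#'
#' @param cr_seq Control-region nucleotide string.
#' @param motif_library Tibble with `block` and `motif` columns (default
#'   [csb_motif_library()]).
#' @param score_fraction Score threshold as a fraction of motif length
#'   (default 0.6, i.e. identity 0.8 for ungapped +1/-1 scoring).
#' @return Tibble with `block`, `start`, `end`, `score`, `identity`,
#'   `found`, ordered by position for found blocks.
#' @export
scan_csb <- function(cr_seq, motif_library = csb_motif_library(),
                     score_fraction = 0.6) {
  motif_library <- tibble::as_tibble(motif_library)
  if (nrow(motif_library) == 0) {
    stop("value error: empty motif library", call. = FALSE)
  }
  cr_seq <- toupper(cr_seq)
  b <- chars(cr_seq)
  n <- length(b)
  hits <- purrr::map_dfr(seq_len(nrow(motif_library)), function(i) {
    block <- motif_library$block[i]
    motif <- chars(toupper(motif_library$motif[i]))
    L <- length(motif)
    if (L > n) {
      return(tibble::tibble(block = block, start = NA_integer_,
                            end = NA_integer_, score = NA_integer_,
                            identity = NA_real_, found = FALSE))
    }
    offs <- 0:(n - L)
    scores <- vapply(offs, function(o) {
      mm <- sum(b[o + seq_len(L)] == motif)
      2L * mm - L  # match +1, mismatch -1
    }, integer(1))
    best <- which.max(scores)
    sc <- scores[best]
    matches <- (sc + L) / 2
    found <- sc >= score_fraction * L
    tibble::tibble(
      block = block,
      start = if (found) offs[best] + 1L else NA_integer_,
      end = if (found) offs[best] + L else NA_integer_,
      score = sc, identity = matches / L, found = found
    )
  })
  dplyr::arrange(hits, !.data$found, .data$start)
}

#' Variable and parsimony-informative sites of an aligned block
#'
#' A site is variable when at least two distinct bases occur in the column;
#' parsimony-informative when at least two bases are each present in at
#' least two sequences. Parsimony-informative sites are a subset of
#' variable sites.
#'
#' @param seqs Character vector of >= 2 equal-length aligned sequences.
#' @return List with `variable` and `parsimony_informative` (integer site
#'   positions) and `n_sites`.
#' @export
#' @examples
#' variable_sites(c("AAT", "AAT", "ATT", "ATA"))
variable_sites <- function(seqs) {
  seqs <- toupper(seqs)
  if (length(seqs) < 2) stop("need >= 2 sequences", call. = FALSE)
  if (length(unique(nchar(seqs))) != 1) {
    stop("alignment error: ragged sequence lengths", call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  is_var <- logical(ncol(mat))
  is_pi <- logical(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    tab <- table(mat[, j])
    tab <- tab[names(tab) %in% c("A", "C", "G", "T")]
    is_var[j] <- length(tab) >= 2
    is_pi[j] <- sum(tab >= 2) >= 2 && length(tab) >= 2
  }
  list(variable = which(is_var), parsimony_informative = which(is_pi),
       n_sites = ncol(mat))
}

#' Control-region report for a genome
#'
#' Runs the tandem-repeat scan and CSB motif scan on the annotated control
#' region of a genome.
#'
#' @param genome A `mito_genome` with sequence and an annotated CR.
#' @param motif_library Passed to [scan_csb()].
#' @param min_period,max_period,min_copies,min_identity Passed to
#'   [find_tandem_repeats()].
#' @return List with `repeats` and `csb` tibbles (CR-relative coordinates).
#' @export
control_region_report <- function(genome, motif_library = csb_motif_library(),
                                  min_period = 10, max_period = 100,
                                  min_copies = 2, min_identity = 0.9) {
  cr <- dplyr::filter(genome$features, .data$ftype == "CR")
  if (nrow(cr) == 0) stop("state error: no control region annotated",
                          call. = FALSE)
  cr_seq <- extract_feature_sequence(genome, cr[1, ])
  list(
    repeats = find_tandem_repeats(cr_seq, min_period, max_period,
                                  min_copies, min_identity),
    csb = scan_csb(cr_seq, motif_library)
  )
}
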