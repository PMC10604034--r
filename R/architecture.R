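# Gene-architecture accounting: junctions, strand usage, gene order.

#' Junction gaps between adjacent features
#'
#' For each adjacent pair of features (in start order) reports the signed
#' intergenic gap: `start(downstream) - end(upstream) - 1`. Positive values
#' are intergenic spacers, negative values overlaps, zero means contiguous.
#' With `include_circular_closure = TRUE` the closing junction from the last
#' feature back to the first is appended, computed modulo the genome length.
#'
#' @param genome A `mito_genome` with at least two features.
#' @param include_circular_closure Append the last->first circular junction
#'   (default FALSE, matching linear table-order accounting).
#' @return A tibble with columns `upstream`, `downstream`, `gap`.
#' @export
#' @examples
#' g <- feature_table_to_genome(tibble::tibble(
#'   gene = c("a", "b"), start = c(1, 11), end = c(10, 20),
#'   strand = "H", ftype = "other"))
#' junction_gaps(g)  # gap 0
junction_gaps <- function(genome, include_circular_closure = FALSE) {
  f <- genome$features
  if (nrow(f) < 2) stop("need at least two features", call. = FALSE)
  if (is.unsorted(f$start)) {
    stop("state error: features are not sorted by start", call. = FALSE)
  }
  up <- f[-nrow(f), ]
  dn <- f[-1, ]
  out <- tibble::tibble(
    upstream = up$gene,
    downstream = dn$gene,
    gap = dn$start - up$end - 1L
  )
  if (include_circular_closure) {
    closing <- (f$start[1] + genome$genome_length - f$end[nrow(f)] - 1L) %%
      genome$genome_length
    out <- dplyr::bind_rows(out, tibble::tibble(
      upstream = f$gene[nrow(f)], downstream = f$gene[1],
      gap = as.integer(closing)
    ))
  }
  out
}

#' Architecture summary of a mitogenome
#'
#' Accounts for the genome's junction structure (overlaps and intergenic
#' spacers with their totals and extremes), strand usage of the 37 genes
#' (control region excluded from gene counts, included in the junction
#' chain), the shortest and longest protein-coding gene, and the signed gene
#' order starting at trnF. Ties for longest spacer/overlap are broken by
#' first occurrence in annotation order.
#'
#' @param genome A `mito_genome`.
#' @param include_circular_closure Passed to [junction_gaps()]; default FALSE
#'   (linear accounting in annotation order).
#' @return An object of class `mito_architecture`: list with `junctions`
#'   (tibble), `summary` (one-row tibble), and `gene_order` (tibble).
#' @export
architecture_summary <- function(genome, include_circular_closure = FALSE) {
  f <- genome$features
  j <- junction_gaps(genome, include_circular_closure)
  ov <- dplyr::filter(j, .data$gap < 0)
  sp <- dplyr::filter(j, .data$gap > 0)
  genes <- dplyr::filter(f, .data$ftype %in% c("PCG", "tRNA", "rRNA"))
  pcg <- genes |>
    dplyr::filter(.data$ftype == "PCG") |>
    dplyr::mutate(size = .data$end - .data$start + 1L)

  longest_of <- function(d, desc = TRUE) {
    if (nrow(d) == 0) return(tibble::tibble(bp = NA_integer_,
                                            junction = NA_character_))
    i <- which.max(abs(d$gap))  # first occurrence wins ties
    tibble::tibble(bp = abs(d$gap[i]),
                   junction = paste0(d$upstream[i], "-", d$downstream[i]))
  }
  lo <- longest_of(ov)
  ls <- longest_of(sp)

  smry <- tibble::tibble(
    n_features = nrow(f),
    n_genes = nrow(genes),
    n_junctions = nrow(j),
    n_overlaps = nrow(ov),
    total_overlap_bp = sum(abs(ov$gap)),
    longest_overlap_bp = lo$bp,
    longest_overlap_junction = lo$junction,
    n_spacers = nrow(sp),
    total_spacer_bp = sum(sp$gap),
    longest_spacer_bp = ls$bp,
    longest_spacer_junction = ls$junction,
    n_contiguous = sum(j$gap == 0),
    strand_h = sum(genes$strand == "H"),
    strand_l = sum(genes$strand == "L"),
    shortest_pcg = if (nrow(pcg)) pcg$gene[which.min(pcg$size)] else NA,
    shortest_pcg_bp = if (nrow(pcg)) min(pcg$size) else NA,
    longest_pcg = if (nrow(pcg)) pcg$gene[which.max(pcg$size)] else NA,
    longest_pcg_bp = if (nrow(pcg)) max(pcg$size) else NA
  )

  structure(
    list(accession = genome$accession, junctions = j, summary = smry,
         gene_order = gene_order(genome)),
    class = "mito_architecture"
  )
}

#' @export
print.mito_architecture <- function(x, ...) {
  s <- x$summary
  cat("<mito_architecture> ", x$accession, "\n",
      "  ", s$n_genes, " genes (H:", s$strand_h, " L:", s$strand_l, "), ",
      s$n_overlaps, " overlaps / ", s$total_overlap_bp, " bp (longest ",
      s$longest_overlap_bp, " bp at ", s$longest_overlap_junction, ")\n",
      "  ", s$n_spacers, " spacers / ", s$total_spacer_bp, " bp (longest ",
      s$longest_spacer_bp, " bp at ", s$longest_spacer_junction, ")\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.mito_architecture <- function(x, ...) x$junctions

#' @export
glance.mito_architecture <- function(x, ...) x$summary

#' Signed gene order of a genome
#'
#' The feature sequence in genomic order, rotated to start at trnF when
#' present, with strand signs (H = +, L = -).
#'
#' @param genome A `mito_genome`.
#' @param start_at Gene to rotate the circular order to (default "trnF").
#' @return Tibble with columns `position`, `gene`, `strand`, `signed`
#'   (e.g. "+trnF", "-trnQ").
#' @export
gene_order <- function(genome, start_at = "trnF") {
  f <- genome$features
  ord <- f$gene
  str <- f$strand
  i <- match(start_at, ord)
  if (!is.na(i) && i > 1) {
    rot <- c(i:length(ord), 1:(i - 1))
    ord <- ord[rot]
    str <- str[rot]
  }
  tibble::tibble(
    position = seq_along(ord), gene = ord, strand = str,
    signed = paste0(ifelse(str == "H", "+", "-"), ord)
  )
}

# strand-aware circular adjacency set; adjacency (a->b) is identified with
# its mirror (-b -> -a) so orientation of reading does not matter
.adjacency_set <- function(order_tbl) {
  sg <- order_tbl$signed
  n <- length(sg)
  nxt <- c(sg[-1], sg[1])
  flip <- function(s) {
    ifelse(startsWith(s, "+"), sub("^\\+", "-", s), sub("^-", "+", s))
  }
  fwd <- paste(sg, nxt, sep = "|")
  rev_ <- paste(flip(nxt), flip(sg), sep = "|")
  canonical <- ifelse(fwd <= rev_, fwd, rev_)
  unique(canonical)
}

#' Compare the gene orders of two genomes
#'
#' Strand-aware comparison of circular gene orders: reports whether the
#' orders are identical (up to rotation), the adjacencies of `a` missing from
#' `b`, the breakpoint distance (count of those adjacencies), and genes
#' present in only one genome. The built-in reference is
#' [canonical_teleost_order()].
#'
#' @param a,b `mito_genome` objects, or tibbles with `gene` and `strand`
#'   columns in genomic order (e.g. `canonical_teleost_order()`).
#' @return A list of class `gene_order_comparison`: `identical` flag,
#'   `breakpoint_distance`, `differing_adjacencies` (tibble), and
#'   `missing_genes` (tibble with `gene`, `absent_from`).
#' @export
compare_gene_order <- function(a, b = canonical_teleost_order()) {
  as_order <- function(x) {
    if (inherits(x, "mito_genome")) return(gene_order(x))
    x <- tibble::as_tibble(x)
    tibble::tibble(position = seq_len(nrow(x)), gene = x$gene,
                   strand = x$strand,
                   signed = paste0(ifelse(x$strand == "H", "+", "-"), x$gene))
  }
  oa <- as_order(a)
  ob <- as_order(b)
  miss <- dplyr::bind_rows(
    tibble::tibble(gene = setdiff(oa$gene, ob$gene), absent_from = "b"),
    tibble::tibble(gene = setdiff(ob$gene, oa$gene), absent_from = "a")
  )
  # breakpoints computed on the shared gene set
  shared <- intersect(oa$gene, ob$gene)
  sa <- dplyr::filter(oa, .data$gene %in% shared)
  sb <- dplyr::filter(ob, .data$gene %in% shared)
  adj_a <- .adjacency_set(sa)
  adj_b <- .adjacency_set(sb)
  diff_ab <- setdiff(adj_a, adj_b)
  split_adj <- function(s) {
    parts <- stringr::str_split_fixed(s, stringr::fixed("|"), 2)
    tibble::tibble(from = parts[, 1], to = parts[, 2])
  }
  structure(
    list(
      identical = length(diff_ab) == 0 && nrow(miss) == 0,
      breakpoint_distance = length(diff_ab),
      differing_adjacencies = split_adj(diff_ab),
      missing_genes = miss
    ),
    class = "gene_order_comparison"
  )
}

#' @export
print.gene_order_comparison <- function(x, ...) {
  cat("<gene_order_comparison> identical: ", x$identical,
      "; breakpoint distance: ", x$breakpoint_distance, "\n", sep = "")
  if (nrow(x$differing_adjacencies) > 0) print(x$differing_adjacencies)
  invisible(x)
}
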