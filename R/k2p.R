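# Kimura two-parameter distances.

.purines <- c("A", "G")
.pyrimidines <- c("C", "T")

#' Kimura 2-parameter distance between two aligned sequences
#'
#' Separates the transition proportion P (A<->G, C<->T) and transversion
#' proportion Q, and returns
#' `d = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))` substitutions/site.
#' Sites carrying a gap, N or other ambiguity in either sequence are
#' excluded pairwise. When the log arguments are non-positive (saturation)
#' `valid` is FALSE and `d` is `NA` while P and Q are still reported. The
#' standard-error estimate follows the usual large-sample (delta-method)
#' formula.
#'
#' @param seq_a,seq_b Equal-length aligned nucleotide strings.
#' @return One-row tibble: `n_sites`, `P`, `Q`, `d`, `se`, `valid`,
#'   `percent` (= 100 d).
#' @export
#' @examples
#' k2p_distance("AAAA", "AAAG")
k2p_distance <- function(seq_a, seq_b) {
  a <- chars(toupper(seq_a))
  b <- chars(toupper(seq_b))
  if (length(a) != length(b)) {
    stop("value error: sequences differ in length", call. = FALSE)
  }
  ok <- a %in% c(.purines, .pyrimidines) & b %in% c(.purines, .pyrimidines)
  a <- a[ok]
  b <- b[ok]
  n <- length(a)
  if (n == 0) stop("value error: zero comparable sites", call. = FALSE)
  diff <- a != b
  ts <- diff & ((a %in% .purines & b %in% .purines) |
                (a %in% .pyrimidines & b %in% .pyrimidines))
  tv <- diff & !ts
  P <- sum(ts) / n
  Q <- sum(tv) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  valid <- w1 > 0 && w2 > 0
  if (valid) {
    d <- -0.5 * log(w1 * sqrt(w2))
    c1 <- 1 / w1
    c2 <- 1 / w2
    c3 <- (c1 + c2) / 2
    se <- sqrt((c1^2 * P + c3^2 * Q - (c1 * P + c3 * Q)^2) / n)
  } else {
    d <- NA_real_
    se <- NA_real_
  }
  tibble::tibble(n_sites = n, P = P, Q = Q, d = d, se = se,
                 valid = valid, percent = 100 * d)
}

#' Pairwise K2P distance matrix of an alignment
#'
#' @param alignment Tibble with `taxon` and `sequence` columns (equal
#'   lengths), or a named character vector.
#' @return A symmetric matrix of K2P distances (substitutions/site).
#'   Saturated pairs yield `NA`.
#' @export
k2p_matrix <- function(alignment) {
  aln <- as_alignment(alignment)
  n <- nrow(aln)
  D <- matrix(0, n, n, dimnames = list(aln$taxon, aln$taxon))
  if (n < 2) return(D)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- k2p_distance(aln$sequence[i], aln$sequence[j])$d
    }
  }
  D
}

# normalize alignment input to tibble(taxon, sequence)
as_alignment <- function(x) {
  if (is.character(x)) {
    x <- tibble::tibble(taxon = names(x), sequence = unname(x))
  }
  x <- tibble::as_tibble(x)
  stopifnot(all(c("taxon", "sequence") %in% names(x)))
  if (length(unique(nchar(x$sequence))) > 1) {
    stop("alignment error: sequences differ in length", call. = FALSE)
  }
  x
}
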