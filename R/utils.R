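# Small shared helpers.

# round half away from zero, at the reporting boundary only
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Reverse complement of a nucleotide string
#'
#' @param seq Character vector of sequences over A,C,G,T,N (case-insensitive).
#' @return Character vector of reverse complements (upper case).
#' @export
#' @examples
#' revcomp("ATGC")
revcomp <- function(seq) {
  vapply(seq, function(s) {
    s <- toupper(s)
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# run code under a temporary RNG state; never perturbs the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# deterministic stage-local sub-seed, kept below 2^31
derive_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000003L) * 2011L + stage * 7919L
}

assert_nucleotides <- function(seq, allow_n = TRUE, what = "sequence") {
  pat <- if (allow_n) "^[ACGTNacgtn]*$" else "^[ACGTacgt]*$"
  ok <- stringr::str_detect(seq, pat)
  if (!all(ok)) {
    stop(what, " contains characters outside {A,C,G,T",
         if (allow_n) ",N", "}", call. = FALSE)
  }
  invisible(TRUE)
}

# split a string into a character vector of single bases
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
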