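# Template-constrained tRNA cloverleaf folding.
#
# The cloverleaf is searched over a rigid template grid rather than by
# free-energy minimization: arm-level claims (cloverleaf vs missing DHU arm,
# Watson-Crick vs wobble pairs) only need a deterministic, enumerable layout.
# Layout, 5'->3':
#   [acceptor 5' : La] [link s1] [D stem Ld | D loop ld | D stem Ld]
#   [link s2] [AC stem Lc | AC loop lc | AC stem Lc] [variable loop v]
#   [T stem Lt | T loop lt | T stem Lt] [acceptor 3' : La]
# with La in 6:7, s1 in 1:2, Ld in 3:4, ld in 4:9, s2 in 0:1, Lc in 4:5,
# lc in {5,7,9}, Lt in 4:5, lt in 4:9 and v absorbing the residual (3..23,
# long variable loops occur in real serine tRNAs).
# Pairing alphabet: A:T, G:C (Watson-Crick, score 2) and G:T (wobble, 1).

.fold_grid <- function(n) {
  g <- expand.grid(La = 6:7, s1 = 1:2, Ld = 3:4, ld = 4:9, s2 = 0:1,
                   Lc = 4:5, lc = c(5L, 7L, 9L), Lt = 4:5, lt = 4:9,
                   KEEP.OUT.ATTRS = FALSE)
  g$v <- n - (2 * g$La + g$s1 + 2 * g$Ld + g$ld + g$s2 +
              2 * g$Lc + g$lc + 2 * g$Lt + g$lt)
  g[g$v >= 3 & g$v <= 23, , drop = FALSE]
}

# pair-score lookup (A,C,G,T x A,C,G,T): WC = 2, G:T wobble = 1, else 0
.pair_score_mat <- matrix(0L, 4, 4, dimnames = list(.bases, .bases))
.pair_score_mat["A", "T"] <- .pair_score_mat["T", "A"] <- 2L
.pair_score_mat["G", "C"] <- .pair_score_mat["C", "G"] <- 2L
.pair_score_mat["G", "T"] <- .pair_score_mat["T", "G"] <- 1L

.pair_label <- function(b5, b3) {
  c("none", "wobble", "WC")[.pair_score_mat[cbind(b5, b3)] + 1L]
}

# stem pair positions for one template; plain integer vectors for speed
.template_pairs <- function(tpl, n) {
  stem <- function(start5, L, loop) {
    list(pos5 = start5 + seq_len(L) - 1L,
         pos3 = start5 + 2L * L + loop - seq_len(L))
  }
  d_start <- tpl$La + tpl$s1 + 1L
  ac_start <- d_start + 2L * tpl$Ld + tpl$ld + tpl$s2
  t_start <- ac_start + 2L * tpl$Lc + tpl$lc + tpl$v
  list(
    acceptor = list(pos5 = seq_len(tpl$La), pos3 = n + 1L - seq_len(tpl$La)),
    d = stem(d_start, tpl$Ld, tpl$ld),
    anticodon = stem(ac_start, tpl$Lc, tpl$lc),
    t = stem(t_start, tpl$Lt, tpl$lt),
    d_loop = c(d_start + tpl$Ld, d_start + tpl$Ld + tpl$ld - 1L),
    ac_loop = c(ac_start + tpl$Lc, ac_start + tpl$Lc + tpl$lc - 1L),
    t_loop = c(t_start + tpl$Lt, t_start + tpl$Lt + tpl$lt - 1L)
  )
}

#' Fold a tRNA gene sequence into a cloverleaf
#'
#' Constrained template search over acceptor (6-7 bp, termini inward), DHU
#' (3-4 bp), anticodon (4-5 bp, anticodon centered in a 5-9 nt loop) and T
#' (4-5 bp) arms. Stem positions only count when they pair within the
#' alphabet {A:T, G:C, G:T}; the structure maximizing total pair score
#' (Watson-Crick 2, wobble 1) is returned. Ties prefer a longer acceptor
#' stem, then more Watson-Crick pairs, then the 5'-most DHU arm, then
#' longer anticodon and T stems (fully deterministic). An arm
#' whose realized stem has fewer than 2 legal pairs is reported in
#' `missing_arms` (the DHU-less mitochondrial serine tRNA case).
#'
#' @param seq tRNA gene sequence (sense strand), 55-95 nt.
#' @param anticodon_hint Optional 3-mer; restricts the search to templates
#'   whose anticodon-loop center equals the hint (falls back to the free
#'   scan when no template matches).
#' @return An object of class `cloverleaf`: list with `seq`, `score`,
#'   `pairs` (tibble: `arm`, `pos5`, `pos3`, `base5`, `base3`, `label`),
#'   `loops` (tibble), `anticodon`, `anticodon_position`, `missing_arms`,
#'   `template` (the winning layout parameters).
#' @export
fold_cloverleaf <- function(seq, anticodon_hint = NULL) {
  seq <- toupper(seq)
  assert_nucleotides(seq, allow_n = FALSE, what = "tRNA sequence")
  n <- nchar(seq)
  if (n < 55 || n > 95) {
    stop("value error: tRNA length ", n, " outside 55..95", call. = FALSE)
  }
  bases <- chars(seq)
  bcode <- match(bases, .bases)
  grid <- .fold_grid(n)
  if (nrow(grid) == 0) stop("fold-failure error: no feasible template",
                            call. = FALSE)

  # anticodon-loop center of every template, vectorized
  mid <- grid$La + grid$s1 + 2L * grid$Ld + grid$ld + grid$s2 + grid$Lc +
    (grid$lc - 3L) %/% 2L + 1L
  if (!is.null(anticodon_hint)) {
    hint <- toupper(chartr("U", "T", anticodon_hint))
    centers <- substring(seq, mid, mid + 2L)
    if (any(centers == hint)) {
      keep <- centers == hint
      grid <- grid[keep, , drop = FALSE]
      mid <- mid[keep]
    }
  }

  M <- .pair_score_mat
  dim(M) <- NULL  # plain vector for fast (b3-1)*4 + b5 indexing
  best_key <- NULL
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    tpl <- as.list(grid[i, ])
    p <- .template_pairs(tpl, n)
    a5 <- c(p$acceptor$pos5, p$d$pos5, p$anticodon$pos5, p$t$pos5)
    a3 <- c(p$acceptor$pos3, p$d$pos3, p$anticodon$pos3, p$t$pos3)
    v <- M[(bcode[a3] - 1L) * 4L + bcode[a5]]
    key <- c(sum(v), tpl$La, sum(v == 2L), -(tpl$La + tpl$s1 + 1L),
             tpl$Lc, tpl$Lt)
    replace <- is.null(best_key)
    if (!replace) {
      cmp <- key - best_key
      nz <- which(cmp != 0)
      replace <- length(nz) > 0 && cmp[nz[1]] > 0
    }
    if (replace) {
      best_key <- key
      best <- list(tpl = tpl, p = p, vals = v, mid = mid[i])
    }
  }

  tpl <- best$tpl
  p <- best$p
  arm_names <- c("acceptor", "D", "anticodon", "T")
  sizes <- c(tpl$La, tpl$Ld, tpl$Lc, tpl$Lt)
  arm_col <- rep(arm_names, sizes)
  a5 <- c(p$acceptor$pos5, p$d$pos5, p$anticodon$pos5, p$t$pos5)
  a3 <- c(p$acceptor$pos3, p$d$pos3, p$anticodon$pos3, p$t$pos3)
  label <- c("none", "wobble", "WC")[best$vals + 1L]
  if (sum(label[arm_col == "acceptor"] != "none") < 4) {
    stop("fold-failure error: no acceptor stem with >= 4 pairs", call. = FALSE)
  }
  pairs <- tibble::tibble(arm = arm_col, pos5 = a5, pos3 = a3,
                          base5 = bases[a5], base3 = bases[a3],
                          label = label)
  legal_d <- sum(label[arm_col == "D"] != "none")
  legal_t <- sum(label[arm_col == "T"] != "none")
  missing <- c(if (legal_d < 2) "D", if (legal_t < 2) "T")

  loops <- tibble::tibble(
    arm = c("D", "anticodon", "T"),
    start = c(p$d_loop[1], p$ac_loop[1], p$t_loop[1]),
    end = c(p$d_loop[2], p$ac_loop[2], p$t_loop[2])
  )
  structure(
    list(
      seq = seq, length = n, score = sum(best$vals),
      pairs = pairs, loops = loops,
      anticodon = substring(seq, best$mid, best$mid + 2L),
      anticodon_position = best$mid,
      missing_arms = missing,
      template = tpl
    ),
    class = "cloverleaf"
  )
}

#' @export
print.cloverleaf <- function(x, ...) {
  prof <- pairing_profile(x)
  cat("<cloverleaf> ", x$length, " nt, score ", x$score,
      ", anticodon ", x$anticodon, " @", x$anticodon_position,
      ", WC ", prof$wc, " / wobble ", prof$wobble,
      if (length(x$missing_arms)) paste0(", missing arms: ",
                                         paste(x$missing_arms, collapse = ",")),
      "\n", sep = "")
  invisible(x)
}

#' @export
tidy.cloverleaf <- function(x, ...) x$pairs

#' Dot-bracket representation of a cloverleaf
#'
#' @param structure A `cloverleaf`.
#' @return A single dot-bracket string (legally paired positions only).
#' @export
as_dot_bracket <- function(structure) {
  db <- rep(".", structure$length)
  ok <- dplyr::filter(structure$pairs, .data$label != "none")
  db[ok$pos5] <- "("
  db[ok$pos3] <- ")"
  paste(db, collapse = "")
}

#' Watson-Crick / wobble pairing profile
#'
#' @param structure A `cloverleaf` from [fold_cloverleaf()].
#' @return One-row tibble with `wc`, `wobble` counts and `all_wc` flag
#'   (TRUE when every legal pair is Watson-Crick).
#' @export
pairing_profile <- function(structure) {
  lab <- structure$pairs$label
  tibble::tibble(
    wc = sum(lab == "WC"),
    wobble = sum(lab == "wobble"),
    all_wc = sum(lab == "wobble") == 0
  )
}

#' Fold every tRNA of a genome and summarise pairing
#'
#' Folds each annotated tRNA (anticodon column used as hint when present)
#' and reports per-tRNA pair counts, wobble usage and missing arms.
#'
#' @param genome A `mito_genome` with sequence.
#' @return A tibble: `gene`, `length`, `score`, `wc`, `wobble`, `all_wc`,
#'   `missing_arms` (comma-separated, "" when none), `anticodon`.
#' @export
trna_profile <- function(genome) {
  trnas <- dplyr::filter(genome$features, .data$ftype == "tRNA")
  purrr::map_dfr(seq_len(nrow(trnas)), function(i) {
    f <- trnas[i, ]
    s <- extract_feature_sequence(genome, f)
    hint <- if (!is.na(f$anticodon) && nzchar(f$anticodon)) f$anticodon else NULL
    st <- fold_cloverleaf(s, anticodon_hint = hint)
    prof <- pairing_profile(st)
    tibble::tibble(
      gene = f$gene, length = st$length, score = st$score,
      wc = prof$wc, wobble = prof$wobble, all_wc = prof$all_wc,
      missing_arms = paste(st$missing_arms, collapse = ","),
      anticodon = st$anticodon
    )
  })
}
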