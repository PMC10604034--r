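# Nucleotide substitution models (JC/K2P/HKY/GTR, optional discrete gamma)
# and the Felsenstein pruning log-likelihood.

.bases <- c("A", "C", "G", "T")
.rate_names <- c("AC", "AG", "AT", "CG", "CT", "GT")

#' Construct a substitution model
#'
#' Time-reversible nucleotide models: JC (equal rates, uniform frequencies),
#' K2P (transition/transversion ratio kappa, uniform frequencies), HKY
#' (kappa + free frequencies) and GTR (six exchangeabilities + free
#' frequencies). Rate matrices are normalized to a mean rate of 1
#' substitution/site. Among-site rate variation uses a k-category discrete
#' gamma (mean-per-category discretization); proportion-invariant is not
#' modelled (its well-known identifiability interplay with +G).
#'
#' @param name One of "JC", "K2P", "HKY", "GTR" (append "+G" to switch
#'   gamma on, e.g. "GTR+G").
#' @param pi Base frequencies in A,C,G,T order (ignored for JC/K2P).
#' @param kappa Transition/transversion rate ratio (K2P/HKY).
#' @param rates Six exchangeabilities in AC,AG,AT,CG,CT,GT order (GTR).
#' @param gamma Use discrete-gamma rate variation (also set by "+G").
#' @param alpha Gamma shape.
#' @param k Number of gamma categories (default 4).
#' @return An object of class `sub_model`.
#' @export
#' @examples
#' substitution_model("K2P", kappa = 4)
substitution_model <- function(name = "GTR", pi = rep(0.25, 4), kappa = 2,
                               rates = rep(1, 6), gamma = FALSE,
                               alpha = 1, k = 4) {
  if (grepl("\\+G$", name)) {
    gamma <- TRUE
    name <- sub("\\+G$", "", name)
  }
  name <- match.arg(name, c("JC", "K2P", "HKY", "GTR"))
  pi <- as.numeric(pi)
  stopifnot(length(pi) == 4, all(pi > 0))
  pi <- pi / sum(pi)
  if (name %in% c("JC", "K2P")) pi <- rep(0.25, 4)
  r <- switch(name,
    JC = rep(1, 6),
    K2P = c(1, kappa, 1, 1, kappa, 1),
    HKY = c(1, kappa, 1, 1, kappa, 1),
    GTR = as.numeric(rates)
  )
  stopifnot(length(r) == 6, all(r > 0))
  names(pi) <- .bases
  names(r) <- .rate_names
  n_free <- switch(name, JC = 0L, K2P = 1L, HKY = 4L, GTR = 8L) +
    as.integer(gamma)
  structure(
    list(name = name, pi = pi, rates = r, kappa = kappa,
         gamma = gamma, alpha = alpha, k = as.integer(k),
         n_free_params = n_free),
    class = "sub_model"
  )
}

#' @export
print.sub_model <- function(x, ...) {
  cat("<sub_model> ", x$name, if (x$gamma) paste0("+G(alpha=", signif(x$alpha, 3),
                                                  ", k=", x$k, ")"),
      "\n  pi: ", paste(signif(x$pi, 3), collapse = " "),
      "\n  rates: ", paste(signif(x$rates, 3), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Rate matrix of a substitution model
#'
#' @param model A `sub_model`.
#' @return 4x4 matrix Q with rows summing to 0 and mean rate 1.
#' @export
rate_matrix <- function(model) {
  S <- matrix(0, 4, 4, dimnames = list(.bases, .bases))
  S["A", "C"] <- S["C", "A"] <- model$rates[["AC"]]
  S["A", "G"] <- S["G", "A"] <- model$rates[["AG"]]
  S["A", "T"] <- S["T", "A"] <- model$rates[["AT"]]
  S["C", "G"] <- S["G", "C"] <- model$rates[["CG"]]
  S["C", "T"] <- S["T", "C"] <- model$rates[["CT"]]
  S["G", "T"] <- S["T", "G"] <- model$rates[["GT"]]
  Q <- S %*% diag(model$pi)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(model$pi * diag(Q))
  Q / mu
}

# eigen decomposition of Q via the pi-symmetrized form; cached per model
.model_eigen <- function(model) {
  Q <- rate_matrix(model)
  sp <- sqrt(model$pi)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  list(values = e$values,
       right = diag(1 / sp) %*% e$vectors,
       left = t(e$vectors) %*% diag(sp))
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param model A `sub_model`.
#' @param t Branch length (expected substitutions/site).
#' @param eig Optional precomputed decomposition (internal use).
#' @return 4x4 stochastic matrix.
#' @export
transition_probs <- function(model, t, eig = NULL) {
  if (is.null(eig)) eig <- .model_eigen(model)
  P <- eig$right %*% diag(exp(eig$values * t)) %*% eig$left
  P[P < 0] <- 0
  dimnames(P) <- list(.bases, .bases)
  P
}

#' Discrete-gamma category rates
#'
#' Mean-per-category discretization of Gamma(shape = alpha, rate = alpha):
#' k equiprobable categories, each represented by its conditional mean.
#' The rates average 1.
#'
#' @param alpha Gamma shape.
#' @param k Number of categories.
#' @return Numeric vector of k rates.
#' @export
discrete_gamma_rates <- function(alpha, k = 4) {
  stopifnot(alpha > 0, k >= 1)
  if (k == 1) return(1)
  bounds <- stats::qgamma(seq(0, 1, length.out = k + 1),
                          shape = alpha, rate = alpha)
  upper <- stats::pgamma(bounds[-1], shape = alpha + 1, rate = alpha)
  lower <- stats::pgamma(bounds[-(k + 1)], shape = alpha + 1, rate = alpha)
  k * (upper - lower)
}

# site-pattern compression: list(states = 4 x npat x ntaxa-ish tip matrices)
.compress_patterns <- function(alignment) {
  aln <- as_alignment(alignment)
  mat <- do.call(rbind, strsplit(toupper(aln$sequence), "", fixed = TRUE))
  rownames(mat) <- aln$taxon
  key <- apply(mat, 2, paste, collapse = "\r")
  first <- !duplicated(key)
  weights <- as.numeric(table(key)[key[first]])
  list(mat = mat[, first, drop = FALSE], weights = weights,
       n_sites = ncol(mat))
}

# one-time preparation: postorder traversal + tip partial matrices
.prep_pruning <- function(tree, pat) {
  nt <- length(tree$tip.label)
  tip_index <- match(rownames(pat$mat), tree$tip.label)
  if (anyNA(tip_index)) stop("tree tips and alignment taxa differ",
                             call. = FALSE)
  npat <- ncol(pat$mat)
  tips <- vector("list", nt)
  for (i in seq_len(nrow(pat$mat))) {
    tl <- matrix(0, 4, npat)
    idx <- match(pat$mat[i, ], .bases)
    known <- !is.na(idx)
    tl[cbind(idx[known], which(known))] <- 1
    tl[, !known] <- 1  # N/gap: uninformative
    tips[[tip_index[i]]] <- tl
  }
  tr <- ape::reorder.phylo(tree, "postorder")
  list(edge = tr$edge, ntip = nt, nnode = tr$Nnode, npat = npat,
       tips = tips, weights = pat$weights, tree = tr)
}

# per-pattern log-likelihood under one rate multiplier; `lens` are branch
# lengths in the prepared postorder edge order
.prune_ll <- function(prep, lens, model, eig, rate = 1) {
  partial <- vector("list", prep$ntip + prep$nnode)
  partial[seq_len(prep$ntip)] <- prep$tips
  logscale <- numeric(prep$npat)
  edge <- prep$edge
  for (e in seq_len(nrow(edge))) {
    parent <- edge[e, 1]
    child <- edge[e, 2]
    P <- transition_probs(model, lens[e] * rate, eig)
    contrib <- P %*% partial[[child]]
    if (is.null(partial[[parent]])) {
      partial[[parent]] <- contrib
    } else {
      p2 <- partial[[parent]] * contrib
      # rescale to dodge underflow on deep trees
      mx <- apply(p2, 2, max)
      mx[mx == 0] <- 1
      partial[[parent]] <- sweep(p2, 2, mx, "/")
      logscale <- logscale + log(mx)
    }
  }
  root <- prep$ntip + 1L
  log(as.numeric(model$pi %*% partial[[root]])) + logscale
}

# summed log-likelihood (gamma-aware) given prepared pruning data
.prep_loglik <- function(prep, lens, model, eig = NULL) {
  if (is.null(eig)) eig <- .model_eigen(model)
  if (!model$gamma) {
    return(sum(prep$weights * .prune_ll(prep, lens, model, eig)))
  }
  rates <- discrete_gamma_rates(model$alpha, model$k)
  lmat <- vapply(rates, function(r) .prune_ll(prep, lens, model, eig, r),
                 numeric(prep$npat))
  lmat <- matrix(lmat, ncol = length(rates))
  m <- apply(lmat, 1, max)
  sum(prep$weights * (m + log(rowMeans(exp(lmat - m)))))
}

#' Felsenstein pruning log-likelihood
#'
#' Log-likelihood of an alignment on a tree under a substitution model,
#' computed by the pruning algorithm over compressed site patterns. With
#' gamma rate variation the site likelihood is averaged over the k discrete
#' category rates before summing site log-likelihoods.
#'
#' @param tree An `ape::phylo` with branch lengths; tips must match the
#'   alignment taxa.
#' @param alignment Tibble with `taxon`, `sequence` (or named character
#'   vector).
#' @param model A `sub_model`.
#' @return The log-likelihood (single number).
#' @export
loglikelihood <- function(tree, alignment, model) {
  pat <- .compress_patterns(alignment)
  if (pat$n_sites == 0) stop("value error: zero-length alignment",
                             call. = FALSE)
  prep <- .prep_pruning(tree, pat)
  .prep_loglik(prep, prep$tree$edge.length, model)
}
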