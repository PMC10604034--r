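# Tree building, supermatrix concatenation, model fitting and BIC ranking.

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (exact on additive matrices). Negative branch
#' lengths are clamped to zero with a warning.
#'
#' @param D Symmetric non-negative distance matrix (>= 3 taxa) or `dist`.
#' @return An unrooted `ape::phylo`.
#' @export
neighbor_joining <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  if (nrow(D) < 3) stop("value error: need >= 3 taxa", call. = FALSE)
  if (any(is.na(D))) stop("value error: NA distances (saturated pairs?)",
                          call. = FALSE)
  if (max(abs(D - t(D))) > 1e-8) stop("value error: matrix not symmetric",
                                      call. = FALSE)
  if (any(D < 0)) stop("value error: negative distances", call. = FALSE)
  tr <- ape::nj(D)
  if (any(tr$edge.length < 0)) {
    warning("negative NJ branch lengths clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' Concatenate per-gene alignments into a supermatrix
#'
#' Column-concatenates the 13 protein-coding-gene alignments (or any gene
#' set) into one supermatrix, recording per-gene column spans. Every taxon
#' must have every gene (no auto-gapping); within a gene all sequences must
#' be aligned (equal length).
#'
#' @param gene_alignments Tibble with columns `gene`, `taxon`, `sequence`.
#' @param gene_order Character vector giving the concatenation order
#'   (default: the 13 PCG names in canonical order of the vocabulary).
#' @return List with `alignment` (tibble `taxon`, `sequence`; taxa in first
#'   appearance order) and `partitions` (tibble `gene`, `start`, `end`).
#' @export
concatenate_pcgs <- function(gene_alignments,
                             gene_order = intersect(.pcg_names,
                                                    unique(gene_alignments$gene))) {
  ga <- tibble::as_tibble(gene_alignments)
  stopifnot(all(c("gene", "taxon", "sequence") %in% names(ga)))
  taxa <- unique(ga$taxon)
  absent_genes <- setdiff(gene_order, unique(ga$gene))
  if (length(absent_genes) > 0) {
    stop("gene(s) absent from input: ", paste(absent_genes, collapse = ", "),
         call. = FALSE)
  }
  missing <- tidyr::expand_grid(gene = gene_order, taxon = taxa) |>
    dplyr::anti_join(ga, by = c("gene", "taxon"))
  if (nrow(missing) > 0) {
    stop("missing gene/taxon pairs: ",
         paste(paste0(missing$taxon, ":", missing$gene), collapse = ", "),
         call. = FALSE)
  }
  lens <- ga |>
    dplyr::filter(.data$gene %in% gene_order) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(n_len = dplyr::n_distinct(nchar(.data$sequence)),
                     len = nchar(.data$sequence)[1], .groups = "drop")
  if (any(lens$n_len > 1)) {
    stop("alignment error: unequal lengths within gene(s): ",
         paste(lens$gene[lens$n_len > 1], collapse = ", "), call. = FALSE)
  }
  lens <- lens[match(gene_order, lens$gene), ]
  ends <- cumsum(lens$len)
  partitions <- tibble::tibble(gene = gene_order,
                               start = ends - lens$len + 1L, end = ends)
  wide <- purrr::map_chr(taxa, function(tx) {
    paste(purrr::map_chr(gene_order, function(g) {
      ga$sequence[ga$gene == g & ga$taxon == tx][1]
    }), collapse = "")
  })
  list(alignment = tibble::tibble(taxon = taxa, sequence = wide),
       partitions = partitions)
}

# ---- model fitting ----------------------------------------------------------

# empirical base frequencies of an alignment
empirical_frequencies <- function(alignment) {
  aln <- as_alignment(alignment)
  all_seq <- paste(aln$sequence, collapse = "")
  n <- vapply(.bases, function(b) stringr::str_count(all_seq,
                                                     stringr::fixed(b)),
              numeric(1))
  if (any(n == 0)) n <- n + 1  # avoid zero frequencies
  n / sum(n)
}

# coordinate-ascent optimization of branch lengths for a fixed model
.optimize_branches <- function(prep, lens, model, eig, sweeps = 2,
                               max_len = 10) {
  for (s in seq_len(sweeps)) {
    for (e in seq_along(lens)) {
      f <- function(x) {
        lens[e] <- x
        -.prep_loglik(prep, lens, model, eig)
      }
      opt <- stats::optimize(f, interval = c(1e-8, max_len), tol = 1e-5)
      lens[e] <- opt$minimum
    }
  }
  list(lens = lens, lnL = .prep_loglik(prep, lens, model, eig))
}

#' Fit a substitution model on a fixed topology
#'
#' Maximum-likelihood fit by coordinate ascent: branch lengths are optimized
#' one at a time (Brent), then the model's free parameters (kappa, GTR
#' exchangeabilities, gamma shape) by bounded one-dimensional or
#' Nelder-Mead search, iterating until the log-likelihood gain falls below
#' `tol`. Base frequencies for HKY/GTR are empirical.
#'
#' @param alignment Tibble with `taxon`, `sequence`.
#' @param tree Starting `phylo` (topology fixed; branch lengths refitted).
#' @param model_name "JC", "K2P", "HKY", "GTR", optionally with "+G".
#' @param max_iter Outer iterations (default 4).
#' @param tol Convergence tolerance in log-units (default 0.01).
#' @return List: `model` (fitted `sub_model`), `tree` (branch lengths
#'   refitted), `lnL`, `n_params` (model free parameters + branch lengths),
#'   `converged`.
#' @export
fit_model <- function(alignment, tree, model_name = "GTR", max_iter = 3,
                      tol = 0.01) {
  pat <- .compress_patterns(alignment)
  gamma <- grepl("\\+G$", model_name)
  base_name <- sub("\\+G$", "", model_name)
  pi <- if (base_name %in% c("HKY", "GTR")) empirical_frequencies(alignment)
        else rep(0.25, 4)
  model <- substitution_model(base_name, pi = pi, kappa = 2,
                              rates = rep(1, 6), gamma = gamma, alpha = 1)
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0.1, nrow(tree$edge))
  tree$edge.length[tree$edge.length <= 0] <- 1e-6
  prep <- .prep_pruning(tree, pat)
  lens <- prep$tree$edge.length

  lnL <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    eig <- .model_eigen(model)
    ob <- .optimize_branches(prep, lens, model, eig)
    lens <- ob$lens

    ll_of <- function(m) .prep_loglik(prep, lens, m)

    if (model$name %in% c("K2P", "HKY")) {
      opt <- stats::optimize(function(lk) {
        -ll_of(substitution_model(model$name, pi = model$pi, kappa = exp(lk),
                                  gamma = model$gamma, alpha = model$alpha))
      }, interval = log(c(0.05, 100)), tol = 1e-3)
      model$kappa <- exp(opt$minimum)
      model <- substitution_model(model$name, pi = model$pi,
                                  kappa = model$kappa, gamma = model$gamma,
                                  alpha = model$alpha)
    } else if (model$name == "GTR") {
      f <- function(lr) {
        -ll_of(substitution_model("GTR", pi = model$pi,
                                  rates = c(exp(lr), 1),
                                  gamma = model$gamma, alpha = model$alpha))
      }
      opt <- stats::optim(log(model$rates[1:5] / model$rates[6]), f,
                          method = "Nelder-Mead",
                          control = list(maxit = 80, reltol = 1e-7))
      model <- substitution_model("GTR", pi = model$pi,
                                  rates = c(exp(opt$par), 1),
                                  gamma = model$gamma, alpha = model$alpha)
    }
    if (model$gamma) {
      opt <- stats::optimize(function(la) {
        m2 <- model
        m2$alpha <- exp(la)
        -ll_of(m2)
      }, interval = log(c(0.05, 50)), tol = 1e-3)
      model$alpha <- exp(opt$minimum)
    }
    new_lnL <- ll_of(model)
    if (new_lnL - lnL < tol) {
      lnL <- max(lnL, new_lnL)
      converged <- TRUE
      break
    }
    lnL <- new_lnL
  }
  out_tree <- prep$tree
  out_tree$edge.length <- lens
  list(model = model, tree = out_tree, lnL = lnL,
       n_params = model$n_free_params + length(lens),
       converged = converged)
}

#' Rank substitution models by BIC
#'
#' Fits each candidate model on the fixed topology ([fit_model()]) and ranks
#' by `BIC = p * ln(n_sites) - 2 * lnL`, where p counts the model's free
#' parameters plus branch lengths. Non-converged fits are flagged but still
#' ranked.
#'
#' @param alignment Tibble with `taxon`, `sequence`.
#' @param tree Baseline `phylo` topology.
#' @param candidate_models Character vector from {JC, K2P, HKY, GTR} x
#'   {"", "+G"}.
#' @return Tibble (class `bic_ranking`) with `model`, `lnL`, `n_params`,
#'   `bic`, `delta_bic`, `converged`, ascending by BIC.
#' @export
bic_rank <- function(alignment, tree,
                     candidate_models = c("JC", "K2P", "HKY", "GTR",
                                          "JC+G", "K2P+G", "HKY+G", "GTR+G")) {
  n_sites <- nchar(as_alignment(alignment)$sequence[1])
  rows <- purrr::map_dfr(candidate_models, function(mn) {
    fit <- fit_model(alignment, tree, mn)
    tibble::tibble(model = mn, lnL = fit$lnL, n_params = fit$n_params,
                   bic = fit$n_params * log(n_sites) - 2 * fit$lnL,
                   converged = fit$converged)
  })
  out <- rows |>
    dplyr::arrange(.data$bic, .data$n_params) |>
    dplyr::mutate(delta_bic = .data$bic - min(.data$bic))
  class(out) <- c("bic_ranking", class(out))
  out
}
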