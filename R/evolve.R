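# Seeded sequence evolution on trees with known parameters.

#' Specify a sequence-evolution simulation
#'
#' @param tree `ape::phylo` with branch lengths (substitutions/site).
#' @param model A `sub_model` (see [substitution_model()]).
#' @param sites Number of sites (>= 1).
#' @param rates Optional per-edge rate multipliers (length = number of
#'   edges, all > 0); branch i evolves at `edge.length[i] * rates[i]`.
#' @param seed Integer seed; same seed gives byte-identical output.
#' @return An `evol_spec` list.
#' @export
evol_spec <- function(tree, model, sites, rates = NULL, seed = 1) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  stopifnot(inherits(model, "sub_model"), sites >= 1)
  if (!is.null(rates)) {
    stopifnot(length(rates) == nrow(tree$edge), all(rates > 0))
  }
  structure(list(tree = tree, model = model, sites = as.integer(sites),
                 rates = rates, seed = as.integer(seed)),
            class = "evol_spec")
}

#' Evolve an alignment on a tree
#'
#' Draws the root sequence from the model's stationary frequencies and
#' evolves it along each branch by the model's transition probabilities at
#' `edge.length * rate`. With a gamma model, each site is assigned one of
#' the k discrete category rates. Deterministic under the spec's seed.
#'
#' @param spec An [evol_spec()].
#' @return List: `alignment` (tibble `taxon`, `sequence`), `tree` (the true
#'   tree), `site_rates` (per-site rate multipliers).
#' @export
evolve_alignment <- function(spec) {
  stopifnot(inherits(spec, "evol_spec"))
  tree <- spec$tree
  model <- spec$model
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  eig <- .model_eigen(model)
  edge_rates <- if (is.null(spec$rates)) rep(1, nrow(tree$edge)) else spec$rates

  with_seed(spec$seed, {
    site_rates <- rep(1, spec$sites)
    cat_rates <- 1
    site_cat <- rep(1L, spec$sites)
    if (model$gamma) {
      cat_rates <- discrete_gamma_rates(model$alpha, model$k)
      site_cat <- sample.int(model$k, spec$sites, replace = TRUE)
      site_rates <- cat_rates[site_cat]
    }
    seqs <- matrix(NA_integer_, nn, spec$sites)
    root <- nt + 1L
    seqs[root, ] <- sample.int(4, spec$sites, replace = TRUE, prob = model$pi)
    tr <- ape::reorder.phylo(tree, "cladewise")  # parents before children
    order_edges <- seq_len(nrow(tr$edge))
    # map reordered edges back to original edge rates
    key <- paste(tree$edge[, 1], tree$edge[, 2])
    rate_of <- edge_rates[match(paste(tr$edge[, 1], tr$edge[, 2]), key)]
    for (e in order_edges) {
      parent <- tr$edge[e, 1]
      child <- tr$edge[e, 2]
      t_e <- tr$edge.length[e] * rate_of[e]
      child_states <- integer(spec$sites)
      for (cat in unique(site_cat)) {
        P <- transition_probs(model, t_e * cat_rates[cat], eig)
        for (b in 1:4) {
          idx <- which(site_cat == cat & seqs[parent, ] == b)
          if (length(idx) > 0) {
            child_states[idx] <- sample.int(4, length(idx), replace = TRUE,
                                            prob = P[b, ])
          }
        }
      }
      seqs[child, ] <- child_states
    }
    aln <- tibble::tibble(
      taxon = tree$tip.label,
      sequence = apply(seqs[seq_len(nt), , drop = FALSE], 1, function(row) {
        paste(.bases[row], collapse = "")
      })
    )
    list(alignment = aln, tree = tree, site_rates = site_rates)
  })
}

#' Simulate a clock-like tree with optional lognormal rate noise
#'
#' Draws an ultrametric coalescent topology and, optionally, multiplies each
#' branch by an independent lognormal rate (meanlog = -sigma^2/2 so the
#' expected rate is 1). The returned object carries both the ultrametric
#' time tree and the rate-distorted branch-length tree.
#'
#' @param n_taxa Number of ingroup tips.
#' @param rate_sigma Lognormal sdlog of per-branch rates (0 = strict clock).
#' @param seed Integer seed.
#' @param depth_scale Multiplier applied to all node depths (default 1).
#' @return List: `time_tree` (ultrametric), `subst_tree` (branch lengths =
#'   time x rate), `rates` (per edge), `true_heights` (node ages of the
#'   time tree).
#' @export
simulate_clock_tree <- function(n_taxa, rate_sigma = 0, seed = 1,
                                depth_scale = 1) {
  with_seed(seed, {
    tt <- ape::rcoal(n_taxa)
    tt$edge.length <- tt$edge.length * depth_scale
    rates <- if (rate_sigma > 0) {
      stats::rlnorm(nrow(tt$edge), meanlog = -rate_sigma^2 / 2,
                    sdlog = rate_sigma)
    } else {
      rep(1, nrow(tt$edge))
    }
    st <- tt
    st$edge.length <- tt$edge.length * rates
    heights <- ape::node.depth.edgelength(tt)
    true_heights <- max(heights) - heights  # ages: tips 0, root max
    list(time_tree = tt, subst_tree = st, rates = rates,
         true_heights = true_heights)
  })
}
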