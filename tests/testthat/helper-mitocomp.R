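# Shared fixtures and independent oracles for the test suite.

fixture_path <- function() {
  system.file("extdata", "psettodes_belcheri_features.tsv",
              package = "mitocomp")
}

fixture_genome <- function() {
  read_feature_table(fixture_path(), accession = "OR231239")
}

# the default simulated genome is used by several files; build it once
.sim_cache <- new.env(parent = emptyenv())
default_sim <- function() {
  if (is.null(.sim_cache$sim)) {
    .sim_cache$sim <- simulate_mitogenome(genome_spec(seed = 42))
  }
  .sim_cache$sim
}

# attach a single-tip outgroup beyond the root of an ultrametric/subst tree
attach_outgroup <- function(tree, label = "OUT", stem_mult = 1.5) {
  root_depth <- max(ape::node.depth.edgelength(tree))
  og <- list(edge = matrix(c(2L, 1L), 1, 2), tip.label = label,
             edge.length = root_depth * stem_mult, Nnode = 1L)
  class(og) <- "phylo"
  ape::bind.tree(tree, og, where = length(tree$tip.label) + 1L)
}

# clade identifier (sorted tip labels) for every internal node, used to map
# nodes between differently-numbered copies of the same topology
clade_keys <- function(tr) {
  nt <- ape::Ntip(tr)
  vapply((nt + 1):(nt + tr$Nnode), function(nd) {
    paste(sort(ape::extract.clade(tr, nd)$tip.label), collapse = ",")
  }, character(1))
}

# independent brute-force likelihood: enumerate all internal-node state
# assignments; transition matrices by scaling-and-squaring series expm,
# not the package's eigen path
brute_force_loglik <- function(tree, alignment, Q, pi, site_rates = 1) {
  series_expm <- function(M) {
    k <- 20
    A <- M / 2^k
    E <- diag(4) + A
    term <- A
    for (i in 2:12) {
      term <- term %*% A / i
      E <- E + term
    }
    for (i in seq_len(k)) E <- E %*% E
    E
  }
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  bases <- c("A", "C", "G", "T")
  mat <- do.call(rbind, strsplit(alignment$sequence, "", fixed = TRUE))
  rownames(mat) <- alignment$taxon
  mat <- mat[tree$tip.label, , drop = FALSE]
  n_sites <- ncol(mat)
  if (length(site_rates) == 1) site_rates <- rep(site_rates, n_sites)
  internal <- (nt + 1):nn
  states <- as.matrix(expand.grid(rep(list(1:4), length(internal))))
  total_ll <- 0
  for (s in seq_len(n_sites)) {
    Ps <- lapply(seq_len(nrow(tree$edge)), function(e) {
      series_expm(Q * tree$edge.length[e] * site_rates[s])
    })
    obs <- match(mat[, s], bases)
    lik <- 0
    for (a in seq_len(nrow(states))) {
      asn <- integer(nn)
      asn[seq_len(nt)] <- obs
      asn[internal] <- states[a, ]
      p <- pi[asn[nt + 1]]
      for (e in seq_len(nrow(tree$edge))) {
        p <- p * Ps[[e]][asn[tree$edge[e, 1]], asn[tree$edge[e, 2]]]
      }
      lik <- lik + p
    }
    total_ll <- total_ll + log(lik)
  }
  total_ll
}

# brute-force gamma-mixture site likelihood (average over category rates)
brute_force_loglik_gamma <- function(tree, alignment, Q, pi, cat_rates) {
  mat <- do.call(rbind, strsplit(alignment$sequence, "", fixed = TRUE))
  n_sites <- ncol(mat)
  per_site <- vapply(seq_len(n_sites), function(s) {
    sub <- tibble::tibble(
      taxon = alignment$taxon,
      sequence = substr(alignment$sequence, s, s)
    )
    liks <- vapply(cat_rates, function(r) {
      exp(brute_force_loglik(tree, sub, Q, pi, site_rates = r))
    }, numeric(1))
    log(mean(liks))
  }, numeric(1))
  sum(per_site)
}

# independent GTR rate matrix builder (order A,C,G,T; mean rate 1)
build_gtr_q <- function(rates, pi) {
  S <- matrix(0, 4, 4)
  S[1, 2] <- S[2, 1] <- rates[1]  # AC
  S[1, 3] <- S[3, 1] <- rates[2]  # AG
  S[1, 4] <- S[4, 1] <- rates[3]  # AT
  S[2, 3] <- S[3, 2] <- rates[4]  # CG
  S[2, 4] <- S[4, 2] <- rates[5]  # CT
  S[3, 4] <- S[4, 3] <- rates[6]  # GT
  Q <- S %*% diag(pi)
  diag(Q) <- -rowSums(Q)
  Q / (-sum(pi * diag(Q)))
}

# independent circular strand-aware adjacency set for breakpoint oracle
oracle_adjacencies <- function(genes, strands) {
  sg <- paste0(ifelse(strands == "H", "+", "-"), genes)
  n <- length(sg)
  flip <- function(s) ifelse(startsWith(s, "+"),
                             sub("^\\+", "-", s), sub("^-", "+", s))
  out <- character(0)
  for (i in seq_len(n)) {
    a <- sg[i]
    b <- sg[if (i == n) 1 else i + 1]
    fwd <- paste(a, b, sep = "|")
    rev_ <- paste(flip(b), flip(a), sep = "|")
    out <- c(out, min(fwd, rev_))
  }
  unique(out)
}

random_seq <- function(n, freq = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = freq),
        collapse = "")
}
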