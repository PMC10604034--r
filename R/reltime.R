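# Relative-rate divergence dating on a fixed rooted topology.
#
# A simplified relative-rate scheme (not a reimplementation of the published
# RelTime variance machinery): relative node heights are obtained tips->root
# by averaging each node's two child path depths, which equalizes the rates
# of sister lineages; calibrations then rescale relative heights to absolute
# ages. Confidence intervals come from a nonparametric bootstrap over sites.

# relative heights of every node of a rooted tree (tips = 0)
.relative_heights <- function(tree) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  h <- numeric(nn)
  tr <- ape::reorder.phylo(tree, "postorder")
  kids <- split(seq_len(nrow(tr$edge)), tr$edge[, 1])
  # postorder guarantees children are done before parents
  parents_in_order <- unique(tr$edge[, 1])
  for (p in parents_in_order) {
    es <- kids[[as.character(p)]]
    depths <- tr$edge.length[es] + h[tr$edge[es, 2]]
    h[p] <- mean(depths)
    # ages must not decrease root->tip; clamp against deeper child
    h[p] <- max(h[p], max(h[tr$edge[es, 2]]))
  }
  h
}

#' Relative-rate divergence dating under calibration constraints
#'
#' Roots the tree on the named outgroup, removes it, computes relative node
#' heights on the ingroup by recursive rate-averaging (each node's height is
#' the mean of its child path depths, proceeding tips to root, clamped so
#' ages stay monotone along every root-to-tip path), then rescales heights
#' so the calibrated nodes satisfy their constraints. A single point
#' calibration fixes the scale exactly; several point calibrations are
#' combined by least squares and each must be satisfied within 10%,
#' otherwise a constraint-conflict error is raised. Interval calibrations
#' (`age_min`/`age_max`) constrain the scale to an intersection of feasible
#' ranges.
#'
#' @param tree Rooted or unrooted `phylo` with branch lengths
#'   (substitutions/site) containing the outgroup tip.
#' @param outgroup Tip label used only for rooting; excluded from height
#'   estimation.
#' @param calibrations Data frame with columns `taxon_a`, `taxon_b` (the
#'   calibrated node is their MRCA) and either `age` (point, MYA) or
#'   `age_min` + `age_max`.
#' @return An object of class `mito_timetree`: list with `tree` (ingroup
#'   phylo), `ages` (per-node absolute ages, MYA), `relative_heights`,
#'   `rates` (per-edge relative rates), `scale`, `calibrations`.
#' @export
reltime_date <- function(tree, outgroup, calibrations) {
  if (!outgroup %in% tree$tip.label) {
    stop("outgroup '", outgroup, "' not in tree", call. = FALSE)
  }
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  ingroup <- ape::drop.tip(rooted, outgroup)
  if (!ape::is.binary(ingroup)) {
    ingroup <- ape::multi2di(ingroup)
  }
  nt <- length(ingroup$tip.label)
  h <- .relative_heights(ingroup)

  cal <- tibble::as_tibble(calibrations)
  stopifnot(all(c("taxon_a", "taxon_b") %in% names(cal)))
  if (!"age" %in% names(cal)) cal$age <- NA_real_
  if (!"age_min" %in% names(cal)) cal$age_min <- NA_real_
  if (!"age_max" %in% names(cal)) cal$age_max <- NA_real_
  cal$node <- purrr::map2_int(cal$taxon_a, cal$taxon_b, function(a, b) {
    if (!all(c(a, b) %in% ingroup$tip.label)) {
      stop("calibration taxa not in ingroup: ", a, ", ", b, call. = FALSE)
    }
    if (a == b) stop("value error: calibration on a tip", call. = FALSE)
    ape::getMRCA(ingroup, c(a, b))
  })
  cal$h <- h[cal$node]
  if (any(cal$h <= 0)) {
    stop("value error: calibration on a zero-height node", call. = FALSE)
  }

  pts <- dplyr::filter(cal, !is.na(.data$age))
  ints <- dplyr::filter(cal, is.na(.data$age))
  s <- NULL
  if (nrow(pts) > 0) {
    s <- sum(pts$age * pts$h) / sum(pts$h^2)  # least squares through origin
    rel_err <- abs(s * pts$h - pts$age) / pts$age
    if (any(rel_err > 0.10)) {
      stop("constraint-conflict error: no positive scale satisfies all ",
           "point calibrations within 10%", call. = FALSE)
    }
  }
  if (nrow(ints) > 0) {
    lo <- max(ints$age_min / ints$h, na.rm = TRUE)
    hi <- min(ints$age_max / ints$h, na.rm = TRUE)
    if (lo > hi) {
      stop("constraint-conflict error: interval calibrations are ",
           "incompatible", call. = FALSE)
    }
    if (is.null(s)) s <- (lo + hi) / 2
    else if (s < lo || s > hi) {
      stop("constraint-conflict error: point and interval calibrations ",
           "are incompatible", call. = FALSE)
    }
  }
  if (is.null(s)) stop("need at least one calibration", call. = FALSE)

  ages <- s * h
  denom <- h[ingroup$edge[, 1]] - h[ingroup$edge[, 2]]
  rates <- ifelse(denom > 0, ingroup$edge.length / (s * denom), NA_real_)
  structure(
    list(tree = ingroup, ages = ages, relative_heights = h, rates = rates,
         scale = s, calibrations = cal),
    class = "mito_timetree"
  )
}

#' @export
print.mito_timetree <- function(x, ...) {
  nt <- length(x$tree$tip.label)
  cat("<mito_timetree> ", nt, " taxa, root age ",
      signif(x$ages[nt + 1], 4), " MYA, scale ", signif(x$scale, 4),
      "\n", sep = "")
  invisible(x)
}

#' Tidy node ages of a time tree
#'
#' @param x A `mito_timetree`.
#' @param ... Unused.
#' @return Tibble with `node`, `label` (tip label or `node_<i>`), `is_tip`,
#'   `age` (MYA), `relative_height`.
#' @export
tidy.mito_timetree <- function(x, ...) {
  nt <- length(x$tree$tip.label)
  nn <- nt + x$tree$Nnode
  tibble::tibble(
    node = seq_len(nn),
    label = c(x$tree$tip.label, paste0("node_", (nt + 1):nn)),
    is_tip = seq_len(nn) <= nt,
    age = x$ages,
    relative_height = x$relative_heights
  )
}

#' One-row summary of a time tree
#'
#' @param x A `mito_timetree`.
#' @param ... Unused.
#' @return Tibble with taxon count, root age, scale and calibration count.
#' @export
glance.mito_timetree <- function(x, ...) {
  nt <- length(x$tree$tip.label)
  tibble::tibble(
    n_taxa = nt,
    root_age = x$ages[nt + 1],
    scale = x$scale,
    n_calibrations = nrow(x$calibrations),
    mean_rate = mean(x$rates, na.rm = TRUE)
  )
}

#' Read a calibration table
#'
#' TSV with columns `taxon_a`, `taxon_b` and `age` (point) or
#' `age_min`/`age_max` (interval), ages in MYA.
#'
#' @param path TSV path.
#' @return Tibble of calibrations for [reltime_date()].
#' @export
read_calibrations <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, comment = "#")
}

# ---- bootstrap CIs ----------------------------------------------------------

# ancestor edge paths for OLS branch lengths
.edge_paths <- function(tree) {
  nt <- length(tree$tip.label)
  parent_of <- integer(nt + tree$Nnode)
  edge_to <- integer(nt + tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    parent_of[tree$edge[e, 2]] <- tree$edge[e, 1]
    edge_to[tree$edge[e, 2]] <- e
  }
  root <- nt + 1L
  lapply(seq_len(nt), function(tip) {
    path <- integer(0)
    v <- tip
    while (v != root) {
      path <- c(path, edge_to[v])
      v <- parent_of[v]
    }
    path
  })
}

# least-squares branch lengths on a fixed topology from a distance matrix
.ols_branch_lengths <- function(tree, D) {
  nt <- length(tree$tip.label)
  paths <- .edge_paths(tree)
  pairs <- utils::combn(nt, 2)
  X <- matrix(0, ncol(pairs), nrow(tree$edge))
  y <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]
    j <- pairs[2, k]
    onpath <- c(setdiff(paths[[i]], paths[[j]]), setdiff(paths[[j]], paths[[i]]))
    X[k, onpath] <- 1
    y[k] <- D[tree$tip.label[i], tree$tip.label[j]]
  }
  beta <- stats::lm.fit(X, y)$coefficients
  beta[is.na(beta) | beta < 0] <- 0
  tree$edge.length <- unname(beta)
  tree
}

#' Bootstrap confidence intervals for node ages
#'
#' Nonparametric bootstrap over alignment sites: each replicate resamples
#' columns, re-estimates branch lengths on the fixed topology by ordinary
#' least squares against the replicate's K2P distance matrix, and re-dates
#' the tree. Seeded and deterministic.
#'
#' @param alignment Tibble with `taxon`, `sequence` (includes the outgroup).
#' @param tree Baseline topology containing the outgroup.
#' @param outgroup,calibrations As in [reltime_date()].
#' @param replicates Number of bootstrap replicates (default 100).
#' @param seed Integer seed (default 1).
#' @return List: `timetree` (point estimate), `ci` (tibble `node`,
#'   `age`, `lower`, `upper` from the 2.5/97.5% replicate quantiles).
#' @export
reltime_bootstrap <- function(alignment, tree, outgroup, calibrations,
                              replicates = 100, seed = 1) {
  aln <- as_alignment(alignment)
  point <- reltime_date(tree, outgroup, calibrations)
  mat <- do.call(rbind, strsplit(aln$sequence, "", fixed = TRUE))
  rownames(mat) <- aln$taxon
  n_sites <- ncol(mat)
  boot_ages <- with_seed(seed, {
    purrr::map(seq_len(replicates), function(r) {
      cols <- sample.int(n_sites, n_sites, replace = TRUE)
      rep_aln <- tibble::tibble(
        taxon = aln$taxon,
        sequence = apply(mat[, cols, drop = FALSE], 1, paste, collapse = "")
      )
      D <- k2p_matrix(rep_aln)
      if (any(is.na(D))) return(NULL)
      tr <- .ols_branch_lengths(tree, D)
      tryCatch(reltime_date(tr, outgroup, calibrations)$ages,
               error = function(e) NULL)
    })
  })
  boot_ages <- purrr::compact(boot_ages)
  amat <- do.call(rbind, boot_ages)
  ci <- tibble::tibble(
    node = seq_along(point$ages),
    age = point$ages,
    lower = apply(amat, 2, stats::quantile, 0.025),
    upper = apply(amat, 2, stats::quantile, 0.975)
  )
  list(timetree = point, ci = ci, n_effective = length(boot_ages))
}
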