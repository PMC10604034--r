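# ggplot2 views of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot junction gaps of an architecture report
#'
#' Lollipop plot of signed intergenic gaps along the genome: spacers up,
#' overlaps down.
#'
#' @param object A `mito_architecture`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mito_architecture <- function(object, ...) {
  j <- dplyr::mutate(object$junctions,
                     idx = dplyr::row_number(),
                     kind = dplyr::case_when(.data$gap > 0 ~ "spacer",
                                             .data$gap < 0 ~ "overlap",
                                             TRUE ~ "contiguous"))
  ggplot2::ggplot(j, ggplot2::aes(x = .data$idx, y = .data$gap,
                                  colour = .data$kind)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$idx, yend = 0)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "junction (annotation order)",
                  y = "signed gap (bp)",
                  title = paste("Junction structure:", object$accession)) +
    ggplot2::theme_minimal()
}

#' Plot partition composition statistics
#'
#' Stacked base-percentage bars per partition with AT/GC skew annotations.
#'
#' @param object A `mito_partition_stats` tibble from [partition_stats()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mito_partition_stats <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    dplyr::select("partition", "pct_A", "pct_T", "pct_G", "pct_C") |>
    tidyr::pivot_longer(-"partition", names_to = "base",
                        names_prefix = "pct_", values_to = "pct")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$partition, y = .data$pct,
                                     fill = .data$base)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "% of partition",
                  title = "Nucleotide composition by partition") +
    ggplot2::theme_minimal()
}

#' Plot a dated tree
#'
#' Simple rectangular time-tree with the age axis in MYA (root left,
#' tips at 0).
#'
#' @param object A `mito_timetree`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mito_timetree <- function(object, ...) {
  tr <- object$tree
  nt <- length(tr$tip.label)
  ages <- object$ages
  # tip y-positions in plotting order, internal nodes midway between children
  ord <- ape::reorder.phylo(tr, "cladewise")
  ypos <- numeric(nt + tr$Nnode)
  ypos[seq_len(nt)] <- match(seq_len(nt), ord$edge[ord$edge[, 2] <= nt, 2])
  tr_post <- ape::reorder.phylo(tr, "postorder")
  for (p in unique(tr_post$edge[, 1])) {
    kids <- tr_post$edge[tr_post$edge[, 1] == p, 2]
    ypos[p] <- mean(ypos[kids])
  }
  seg <- tibble::tibble(
    x = -ages[tr$edge[, 1]], xend = -ages[tr$edge[, 2]],
    y = ypos[tr$edge[, 2]], yend = ypos[tr$edge[, 2]],
    py = ypos[tr$edge[, 1]]
  )
  tips <- tibble::tibble(x = -ages[seq_len(nt)], y = ypos[seq_len(nt)],
                         label = tr$tip.label)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, xend = .data$x,
                                       y = .data$py, yend = .data$y)) +
    ggplot2::geom_text(data = tips,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$label),
                       hjust = -0.05, size = 3) +
    ggplot2::scale_x_continuous(labels = function(v) -v,
                                expand = ggplot2::expansion(mult = c(0.02, 0.2))) +
    ggplot2::labs(x = "age (MYA)", y = NULL, title = "Dated phylogeny") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid.major.y = ggplot2::element_blank())
}
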