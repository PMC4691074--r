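#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of the main result types:
#' motif-type censuses as bars, expression results as a log2 fold-change
#' tile map with significance stars, and `plot_chromosome_map()` draws
#' gene positions along chromosomes.
#'
#' @param object a result object.
#' @param ... unused.
#' @return a ggplot object.
#' @name vqfam-plots
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname vqfam-plots
#' @exportS3Method ggplot2::autoplot
autoplot.vq_motif_census <- function(object, ...) {
  ggplot2::ggplot(object$census,
                  ggplot2::aes(x = stats::reorder(.data$type_code, -.data$n),
                               y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "motif type code", y = "proteins",
                  title = sprintf("VQ motif types (%d/%d proteins with a hit)",
                                  object$n_proteins_with_hit,
                                  object$n_proteins_scanned)) +
    ggplot2::theme_minimal()
}

#' @rdname vqfam-plots
#' @exportS3Method ggplot2::autoplot
autoplot.vq_expression <- function(object, ...) {
  df <- tidy(object) %>%
    mutate(cell = paste(.data$condition, .data$timepoint, sep = ":"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cell, y = .data$gene,
                                   fill = .data$log2_rq)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars), size = 3) +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "log2 fold") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @param genes a gene-model tibble.
#' @rdname vqfam-plots
#' @export
plot_chromosome_map <- function(genes) {
  df <- genes %>% mutate(mb = (.data$start + .data$end) / 2e6)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$chrom, y = .data$mb)) +
    ggplot2::geom_point(shape = 95, size = 6, colour = "firebrick") +
    ggplot2::geom_text(ggplot2::aes(label = .data$gene_name),
                       hjust = -0.15, size = 2.5) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = "position (Mb)") +
    ggplot2::theme_minimal()
}

#' Tidy a tree into an edge table
#'
#' @param x a `vq_phylo` tree.
#' @param ... unused.
#' @return a tibble with one row per edge: `parent`, `node`, `length`,
#'   `label` (tip label or internal support), `is_tip`.
#' @exportS3Method generics::tidy
tidy.vq_phylo <- function(x, ...) {
  ntip <- length(x$tip.label)
  lab <- character(ntip + x$Nnode)
  lab[seq_len(ntip)] <- x$tip.label
  if (!is.null(x$node.label)) lab[ntip + seq_len(x$Nnode)] <- x$node.label
  tibble(
    parent = x$edge[, 1], node = x$edge[, 2],
    length = x$edge.length %||% rep(NA_real_, nrow(x$edge)),
    label = lab[x$edge[, 2]],
    is_tip = x$edge[, 2] <= ntip
  )
}

#' @exportS3Method generics::glance
glance.vq_phylo <- function(x, ...) {
  sup <- suppressWarnings(as.numeric(x$node.label))
  tibble(
    n_tips = length(x$tip.label),
    n_internal = x$Nnode,
    total_length = sum(x$edge.length %||% NA_real_),
    min_support = if (all(is.na(sup))) NA_real_ else min(sup, na.rm = TRUE)
  )
}
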