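#' Headline family report
#'
#' Pure tally over previously computed stage outputs (nothing is
#' recomputed): gene counts, intronless census, small-protein count,
#' motif-type census, per-chromosome counts, subgenome counts, per-locus
#' copy-number histogram, tandem/segmental totals and Mw/pI ranges --
#' whichever inputs are supplied.
#'
#' @param genes gene-model tibble (required).
#' @param props optional [protein_props()] result.
#' @param census optional [classify_census()] result.
#' @param synteny optional synteny tibble.
#' @param duplications optional [classify_duplications()] result.
#' @param small_protein_max length cutoff for the "small protein" tally
#'   (default 300 aa).
#' @return an object of class `vq_report`: a named list of tibbles and
#'   scalars.
#' @export
family_report <- function(genes, props = NULL, census = NULL,
                          synteny = NULL, duplications = NULL,
                          small_protein_max = 300L) {
  if (is.null(genes) || nrow(genes) == 0L) vq_abort("empty inputs")
  if (!is.null(props) && anyDuplicated(props$id)) {
    vq_abort(paste0("conflicting protein ids: ",
                    paste(props$id[duplicated(props$id)], collapse = ", ")))
  }
  if (anyDuplicated(genes$gene_name)) {
    vq_abort(paste0("conflicting gene ids: ",
                    paste(genes$gene_name[duplicated(genes$gene_name)],
                          collapse = ", ")))
  }
  lengths_aa <- if (!is.null(props)) props$length_aa else
    protein_length_from_cds(genes$cds_length)
  out <- list(
    n_genes = nrow(genes),
    intronless = intronless_census(genes),
    n_small_proteins = sum(lengths_aa <= small_protein_max),
    protein_length_range = range(lengths_aa),
    chromosome_census = chromosome_census(genes)
  )
  if (!is.null(props)) {
    out$mw_range_kda <- round(range(props$mw_da) / 1000, 1)
    out$pi_range <- range(props$pi)
  }
  if (!is.null(census)) out$motif_census <- tidy(census)
  if (!is.null(synteny)) {
    tab <- subgenome_tabulate(synteny)
    out$subgenome_counts <- tab$subgenome_counts
    out$copy_histogram <- tab$copy_histogram
    out$n_anchored_loci <- tab$n_anchored_loci
  }
  if (!is.null(duplications)) out$duplication <- glance(duplications)
  structure(out, class = "vq_report")
}

#' @export
print.vq_report <- function(x, ...) {
  cat(sprintf("family report: %d genes; %d/%d intronless; %d proteins <= 300 aa\n",
              x$n_genes, x$intronless$n_intronless, x$intronless$n_total,
              x$n_small_proteins))
  cat("chromosome census:\n")
  print(x$chromosome_census, n = Inf)
  if (!is.null(x$motif_census)) { cat("motif census:\n"); print(x$motif_census) }
  if (!is.null(x$subgenome_counts)) {
    cat("subgenome counts:\n"); print(x$subgenome_counts)
  }
  if (!is.null(x$duplication)) { cat("duplication:\n"); print(x$duplication) }
  invisible(x)
}

#' Write a report as JSON and TSV
#'
#' @param report a [family_report()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  readr::write_tsv(report$chromosome_census,
                   file.path(dir, "chromosome_census.tsv"))
  invisible(dir)
}
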