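#' Read gene models from a GFF3 file
#'
#' Builds one gene-model row per mRNA: the mRNA span, its strand, its CDS
#' intervals sorted by start (exposed in a list-column), and the CDS length
#' as the sum of interval lengths. GFF3 coordinates are natively 1-based
#' inclusive and are used as-is.
#'
#' A CDS feature without a `Parent` attribute, or overlapping CDS intervals
#' under one mRNA, are errors.
#'
#' @param path path to a GFF3 file.
#' @return a tibble with columns `gene_name`, `locus_id`, `chrom`, `strand`,
#'   `start`, `end`, `cds_length`, `exons` (list of two-column matrices).
#' @export
read_gff3 <- function(path) {
  g <- rtracklayer::readGFF(path)
  g <- as.data.frame(g)
  mrna <- g[g$type %in% c("mRNA", "transcript"), , drop = FALSE]
  cds <- g[g$type == "CDS", , drop = FALSE]
  if (nrow(mrna) == 0L) vq_abort("no mRNA features in GFF3")
  parent_of <- function(df) {
    p <- df$Parent
    if (is.null(p)) return(rep(NA_character_, nrow(df)))
    if (is.list(p)) p <- vapply(p, function(x) {
      if (length(x) == 0L) NA_character_ else as.character(x[[1]])
    }, character(1))
    as.character(p)
  }
  cds_parent <- parent_of(cds)
  if (nrow(cds) > 0L && anyNA(cds_parent)) {
    vq_abort("CDS feature without Parent attribute")
  }
  rows <- lapply(seq_len(nrow(mrna)), function(i) {
    id <- as.character(mrna$ID[i])
    ex <- cds[cds_parent == id, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) > 1L && any(ex$start[-1] <= ex$end[-nrow(ex)])) {
      vq_abort(paste0("overlapping CDS intervals in mRNA ", id))
    }
    gene <- parent_of(mrna[i, , drop = FALSE])
    if (length(gene) == 0L || is.na(gene)) gene <- id
    tibble(
      gene_name = id, locus_id = gene,
      chrom = as.character(mrna$seqid[i]),
      strand = as.character(mrna$strand[i]),
      start = as.integer(mrna$start[i]), end = as.integer(mrna$end[i]),
      cds_length = if (nrow(ex) > 0L) {
        as.integer(sum(ex$end - ex$start + 1L))
      } else NA_integer_,
      exons = list(cbind(start = as.integer(ex$start),
                         end = as.integer(ex$end)))
    )
  })
  bind_rows(rows)
}
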