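#' Intron counts for gene models
#'
#' With an exon list the intron count is exact (`|exons| - 1`). Without one,
#' intronless status is inferred from coordinates: a genomic span equal to
#' the CDS length can hold no intron, while a longer span implies at least
#' one (`intron_min = 1`, `intron_count = NA`). The inference is exact for
#' locus tables whose `start`-`end` column spans the CDS only (no UTRs),
#' which holds for every intronless row of the family table shipped with
#' the package.
#'
#' @param genes a gene-model tibble (see [read_gene_table()] /
#'   [read_gff3()]); an `exons` list-column is used when present.
#' @return the input with columns `span`, `intron_count` (integer, `NA`
#'   when only a lower bound is known), `intron_min` (lower bound) and
#'   `intronless` (logical) appended.
#' @export
intron_count <- function(genes) {
  genes <- as_tibble(genes)
  span <- genes$end - genes$start + 1L
  if ("exons" %in% names(genes)) {
    n_ex <- vapply(genes$exons, function(e) {
      if (is.null(e) || nrow(e) == 0L) NA_integer_ else nrow(e)
    }, integer(1))
  } else {
    n_ex <- rep(NA_integer_, nrow(genes))
  }
  inferred_zero <- span == genes$cds_length
  cnt <- ifelse(!is.na(n_ex), n_ex - 1L,
                ifelse(inferred_zero, 0L, NA_integer_))
  genes %>% mutate(
    span = span,
    intron_count = as.integer(cnt),
    intron_min = ifelse(!is.na(cnt), as.integer(cnt), 1L),
    intronless = ifelse(!is.na(cnt), cnt == 0L, FALSE)
  )
}

#' Count intronless genes
#'
#' @param genes a gene-model tibble.
#' @return a tibble with one row: `n_intronless`, `n_total`,
#'   `pct_intronless`.
#' @export
#' @examples
#' intronless_census(table1_fixture())
intronless_census <- function(genes) {
  if (nrow(genes) == 0L) vq_abort("empty gene list")
  st <- intron_count(genes)
  tibble(
    n_intronless = sum(st$intronless),
    n_total = nrow(st),
    pct_intronless = round(100 * sum(st$intronless) / nrow(st), 1)
  )
}
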