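#' Packaged family locus table
#'
#' The 57-gene VQ family locus table for Chinese cabbage (gene names, locus
#' ids, chromosomes, strands, genomic spans and CDS lengths), transcribed
#' from the published family table and shipped as a plain-text fixture.
#' Location strings are kept exactly as printed -- including four rows with
#' misplaced thousands separators -- so the fixture also exercises the
#' tolerant span parser.
#'
#' @return a gene-model tibble (see [read_gene_table()]).
#' @export
#' @examples
#' nrow(table1_fixture()) # 57
table1_fixture <- function() {
  read_gene_table(vq_asset("vq_gene_table.tsv"))
}

#' Packaged synteny / subgenome table
#'
#' One row per family member anchored (or not) to a reference-species
#' locus, with its ancestral-karyotype block and subgenome label (LF, MF1
#' or MF2). Three members carry no reference anchor and form singleton
#' groups.
#'
#' @return a synteny tibble (see [read_synteny_table()]).
#' @export
#' @examples
#' dplyr::count(table2_fixture(), subgenome)
table2_fixture <- function() {
  read_synteny_table(vq_asset("vq_synteny.tsv"))
}
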