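#' Ortholog-based family naming
#'
#' Maps each query protein to its best-scoring reference protein by global
#' alignment score and derives family names from the reference gene names:
#' queries sharing a reference get `-1`, `-2`, ... suffixes ordered by
#' descending percent similarity (ties broken by locus id, lexicographic);
#' a query that is the sole hit of its reference gets the bare name.
#'
#' @param br_proteins query proteome: data frame with `id`, `sequence`
#'   (ids are locus ids, e.g. `Bra007265`).
#' @param ref_proteins reference proteome: data frame with `id`, `sequence`
#'   (ids are family gene names, e.g. `AtVQ23`).
#' @param prefix prefix replacing the reference species prefix in assigned
#'   names (default `"BrVQ"`).
#' @inheritParams global_align
#' @return a tibble: `br_gene` (query id), `ref_gene`, `similarity_pct`,
#'   `assigned_name`.
#' @export
assign_names <- function(br_proteins, ref_proteins, prefix = "BrVQ",
                         matrix_name = "BLOSUM62",
                         gap_open = 10, gap_extend = 0.5) {
  if (nrow(br_proteins) == 0L || nrow(ref_proteins) == 0L) {
    vq_abort("empty proteome")
  }
  best <- purrr::map(seq_len(nrow(br_proteins)), function(i) {
    scores <- purrr::map(seq_len(nrow(ref_proteins)), function(j) {
      pa <- global_align(br_proteins$sequence[i], ref_proteins$sequence[j],
                         matrix_name, gap_open, gap_extend)
      list(score = pa$score, sim = pa$similarity_pct)
    })
    sc <- map_dbl(scores, "score")
    j <- which.max(sc)
    tibble(br_gene = br_proteins$id[i],
           ref_gene = ref_proteins$id[j],
           similarity_pct = scores[[j]]$sim)
  }) %>% bind_rows()
  # family number from the reference name, e.g. AtVQ23 -> 23
  fam <- stringr::str_extract(best$ref_gene, "\\d+[A-Za-z]*$")
  best %>%
    mutate(family = fam) %>%
    group_by(.data$ref_gene) %>%
    arrange(desc(.data$similarity_pct), .data$br_gene, .by_group = TRUE) %>%
    mutate(assigned_name = if (n() == 1L) paste0(prefix, .data$family) else
      paste0(prefix, .data$family, "-", row_number())) %>%
    ungroup() %>%
    arrange(.data$assigned_name) %>%
    select("br_gene", "ref_gene", "similarity_pct", "assigned_name")
}

#' Per-chromosome gene counts
#'
#' @param genes a gene-model tibble with a `chrom` column.
#' @param scaffold_regex chromosomes matching this pattern are reported as
#'   scaffolds (`is_scaffold = TRUE`) rather than chromosomes.
#' @return a tibble `chrom`, `n`, `is_scaffold`, sorted by descending count
#'   then chromosome name.
#' @export
#' @examples
#' chromosome_census(table1_fixture())
chromosome_census <- function(genes, scaffold_regex = "(?i)^scaffold") {
  if (nrow(genes) == 0L) vq_abort("empty gene list")
  genes %>%
    count(.data$chrom, name = "n") %>%
    mutate(is_scaffold = stringr::str_detect(.data$chrom, scaffold_regex)) %>%
    arrange(.data$is_scaffold, desc(.data$n), .data$chrom)
}

#' Classify duplication mode within locus groups
#'
#' Within each multi-member locus group, every unordered gene pair is
#' *tandem* when both genes sit on the same chromosome with an intergenic
#' gap of at most `tandem_max_gap` bp, and *segmental* otherwise. A gene
#' participating in at least one tandem pair is labelled `tandem` and
#' excluded from the segmental gene count; the remaining grouped genes with
#' at least one counterpart are labelled `segmental`; singleton-group genes
#' are `none`.
#'
#' @param locus_groups a synteny tibble from [read_synteny_table()] /
#'   [table2_fixture()] (needs `gene_name`, `group_id`).
#' @param genes a gene-model tibble with coordinates for every group
#'   member.
#' @param tandem_max_gap maximum intergenic gap (bp) for a tandem call
#'   (default 25000).
#' @return a list of class `vq_duplication`: `pairs` (tibble `gene_a`,
#'   `gene_b`, `mode`, `chrom_a`, `chrom_b`, `gap_bp`, `group_id`),
#'   `genes` (tibble `gene_name`, `label`), and `summary` (one-row tibble
#'   `n_tandem_pairs`, `n_tandem_genes`, `n_segmental_genes`).
#' @export
classify_duplications <- function(locus_groups, genes,
                                  tandem_max_gap = 25000) {
  lg <- as_tibble(locus_groups)
  if (!"group_id" %in% names(lg)) {
    lg <- lg %>% mutate(group_id = ifelse(.data$ref_locus == "",
                                          paste0("unanchored:", .data$gene_name),
                                          .data$ref_locus))
  }
  missing <- setdiff(lg$gene_name, genes$gene_name)
  if (length(missing) > 0L) {
    vq_abort(paste0("no coordinates for group member(s): ",
                    paste(missing, collapse = ", ")))
  }
  coords <- genes %>% select("gene_name", "chrom", "start", "end")
  lg <- lg %>% left_join(coords, by = "gene_name")
  pairs <- lg %>%
    group_by(.data$group_id) %>%
    filter(n() > 1L) %>%
    summarise(pair = list({
      gs <- sort(.data$gene_name)
      if (length(gs) < 2L) tibble() else {
        idx <- utils::combn(length(gs), 2L)
        tibble(gene_a = gs[idx[1, ]], gene_b = gs[idx[2, ]])
      }
    }), .groups = "drop") %>%
    tidyr::unnest("pair")
  if (nrow(pairs) > 0L) {
    pairs <- pairs %>%
      left_join(coords, by = c(gene_a = "gene_name")) %>%
      rename(chrom_a = "chrom", start_a = "start", end_a = "end") %>%
      left_join(coords, by = c(gene_b = "gene_name")) %>%
      rename(chrom_b = "chrom", start_b = "start", end_b = "end") %>%
      mutate(
        gap_bp = ifelse(.data$chrom_a == .data$chrom_b,
                        pmax(0L, pmax(.data$start_a, .data$start_b) -
                               pmin(.data$end_a, .data$end_b) - 1L),
                        NA_integer_),
        mode = ifelse(!is.na(.data$gap_bp) & .data$gap_bp <= tandem_max_gap,
                      "tandem", "segmental")
      ) %>%
      select("gene_a", "gene_b", "mode", "chrom_a", "chrom_b", "gap_bp",
             "group_id")
  } else {
    pairs <- tibble(gene_a = character(), gene_b = character(),
                    mode = character(), chrom_a = character(),
                    chrom_b = character(), gap_bp = integer(),
                    group_id = character())
  }
  tandem_genes <- unique(c(pairs$gene_a[pairs$mode == "tandem"],
                           pairs$gene_b[pairs$mode == "tandem"]))
  grouped_genes <- unique(c(pairs$gene_a, pairs$gene_b))
  gene_labels <- lg %>%
    distinct(.data$gene_name) %>%
    mutate(label = dplyr::case_when(
      .data$gene_name %in% tandem_genes ~ "tandem",
      .data$gene_name %in% grouped_genes ~ "segmental",
      TRUE ~ "none"
    ))
  structure(
    list(pairs = pairs, genes = gene_labels,
         summary = tibble(
           n_tandem_pairs = sum(pairs$mode == "tandem"),
           n_tandem_genes = length(tandem_genes),
           n_segmental_genes = sum(gene_labels$label == "segmental")
         )),
    class = "vq_duplication"
  )
}

#' @export
print.vq_duplication <- function(x, ...) {
  cat(sprintf("duplication calls: %d tandem pair(s), %d tandem gene(s), %d segmental gene(s)\n",
              x$summary$n_tandem_pairs, x$summary$n_tandem_genes,
              x$summary$n_segmental_genes))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.vq_duplication <- function(x, ...) x$genes

#' @exportS3Method generics::glance
glance.vq_duplication <- function(x, ...) x$summary

#' Subgenome copy-number tabulation
#'
#' Counts member genes per subgenome across all locus groups and builds the
#' per-locus copy-number histogram over groups anchored to a reference
#' locus (unanchored members are excluded from the histogram but counted
#' in the subgenome totals).
#'
#' @inheritParams classify_duplications
#' @return a list: `subgenome_counts` (tibble `subgenome`, `n`),
#'   `copy_histogram` (tibble `copies`, `n_loci`), `n_anchored_loci`,
#'   `n_member_genes`.
#' @export
subgenome_tabulate <- function(locus_groups) {
  lg <- as_tibble(locus_groups)
  if (nrow(lg) == 0L) vq_abort("empty locus group table")
  ok <- c("LF", "MF1", "MF2", "unassigned")
  bad <- setdiff(unique(lg$subgenome), ok)
  if (length(bad) > 0L) {
    vq_abort(paste0("unknown subgenome label: ", paste(bad, collapse = ", ")))
  }
  anchored <- lg %>% filter(.data$ref_locus != "")
  hist <- anchored %>%
    count(.data$ref_locus, name = "copies") %>%
    count(.data$copies, name = "n_loci")
  list(
    subgenome_counts = lg %>% count(.data$subgenome, name = "n") %>%
      arrange(factor(.data$subgenome, levels = ok)),
    copy_histogram = hist,
    n_anchored_loci = dplyr::n_distinct(anchored$ref_locus),
    n_member_genes = dplyr::n_distinct(lg$gene_name)
  )
}
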