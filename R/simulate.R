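#' Configuration for the synthetic family simulator
#'
#' Defaults emulate the statistical structure of the Chinese cabbage VQ
#' family: 28 reference loci with a 10/11/7 one/two/three-copy split, the
#' observed motif-type frequencies, a single tandem pair among the
#' multi-copy loci, ten chromosomes, protein lengths spanning the observed
#' 93-568 aa range, and a three-replicate qPCR design with Gaussian
#' replicate noise of 0.2 cycles on dCt.
#'
#' @param seed integer RNG seed.
#' @param n_ref_loci number of reference loci.
#' @param copy_distribution named probabilities over copy numbers
#'   `"1"`, `"2"`, `"3"`.
#' @param motif_type_distribution named probabilities over motif type
#'   codes.
#' @param tandem_fraction probability that a multi-copy locus carries a
#'   tandem pair (copies within 5 kb on one chromosome); remaining copies
#'   are placed on distinct chromosomes.
#' @param n_chromosomes,chromosome_length genome layout (bp).
#' @param protein_length_range min/max ancestral protein length (aa).
#' @param substitution_rate per-site substitution probability between
#'   copies of a locus.
#' @param n_intron_genes number of genes given 1-3 planted introns.
#' @param protect_motif if `TRUE` (default) the motif window never mutates,
#'   so planted type counts are exact; `FALSE` allows motif erosion for
#'   robustness testing.
#' @param conditions,timepoints,n_replicates,noise_sd,lfc_values qPCR
#'   design: the first condition x first timepoint cell is the calibrator;
#'   each other cell gets a planted log2 fold change drawn from
#'   `lfc_values`.
#' @return a list of class `vq_sim_config`.
#' @export
simulation_config <- function(
    seed = 1L,
    n_ref_loci = 28L,
    copy_distribution = c(`1` = 10 / 28, `2` = 11 / 28, `3` = 7 / 28),
    motif_type_distribution =
      c(LTG = 43, FTG = 8, VTG = 3, LTS = 1, LTV = 1, YTG = 1) / 57,
    tandem_fraction = 1 / 18,
    n_chromosomes = 10L,
    chromosome_length = 3e7,
    protein_length_range = c(93L, 568L),
    substitution_rate = 0.12,
    n_intron_genes = 3L,
    protect_motif = TRUE,
    conditions = c("CK", "PEG"),
    timepoints = c("0h", "3h", "24h"),
    n_replicates = 3L,
    noise_sd = 0.2,
    lfc_values = c(-3, -2, 0, 2, 3)) {
  stopifnot(abs(sum(copy_distribution) - 1) < 1e-8,
            abs(sum(motif_type_distribution) - 1) < 1e-8,
            n_replicates >= 1L, substitution_rate >= 0,
            substitution_rate < 1)
  structure(as.list(environment()), class = "vq_sim_config")
}

codon_map <- c(
  A = "GCA", C = "TGC", D = "GAC", E = "GAA", F = "TTC", G = "GGA",
  H = "CAC", I = "ATA", K = "AAA", L = "CTA", M = "ATG", N = "AAC",
  P = "CCA", Q = "CAA", R = "AGA", S = "AGC", T = "ACA", V = "GTA",
  W = "TGG", Y = "TAC", X = "NNN"
)

# back-translate with a fixed (alphabetically first) codon per residue,
# plus a TAA stop, so CDS fixtures are deterministic
back_translate <- function(protein) {
  paste0(paste(codon_map[strsplit(protein, "")[[1]]], collapse = ""), "TAA")
}

# one protein with exactly one strict VQ window of the given type
plant_motif_protein <- function(len, type_code, max_tries = 100L) {
  alpha <- aa_alphabet()
  for (t in seq_len(max_tries)) {
    pos <- sample.int(len - 10L, 1L) + 1L
    bg <- sample(alpha, len, replace = TRUE)
    window <- c("F", sample(alpha, 3L, TRUE), "V", "Q", sample(alpha, 1L),
                strsplit(type_code, "")[[1]])
    bg[pos:(pos + 9L)] <- window
    s <- paste(bg, collapse = "")
    hits <- scan_vq(tibble(id = "x", sequence = s))
    if (nrow(hits) == 1L && hits$start == pos &&
        hits$type_code == type_code) {
      return(list(sequence = s, motif_start = pos))
    }
  }
  vq_abort("could not plant a unique motif window")
}

mutate_copy <- function(sequence, rate, motif_start, protect,
                        type_code, max_tries = 100L) {
  alpha <- aa_alphabet()
  aa <- strsplit(sequence, "")[[1]]
  protected <- if (protect) motif_start:(motif_start + 9L) else integer(0)
  for (t in seq_len(max_tries)) {
    out <- aa
    hit <- runif(length(aa)) < rate
    hit[protected] <- FALSE
    out[hit] <- sample(alpha, sum(hit), replace = TRUE)
    s <- paste(out, collapse = "")
    if (!protect) return(s)
    hits <- scan_vq(tibble(id = "x", sequence = s))
    if (nrow(hits) == 1L && hits$type_code == type_code) return(s)
  }
  vq_abort("could not derive a copy with an intact unique motif")
}

#' Simulate a gene family with planted ground truth
#'
#' For each reference locus the generator draws a copy number, builds an
#' ancestral protein with exactly one planted VQ window of a drawn type,
#' derives copies by point substitution (motif window protected by
#' default), back-translates to CDS with fixed codons, places the copies
#' on chromosomes (tandem pairs within 5 kb, segmental copies on distinct
#' chromosomes), assigns subgenome labels, optionally inserts introns into
#' a few genes, and simulates a replicate-level Ct table under planted
#' log2 fold changes. Everything planted is recorded in `$truth`.
#'
#' @param cfg a [simulation_config()].
#' @return a list of class `vq_simulation`: tibbles `proteins`, `cds`,
#'   `genes` (with `exons` list-column), `synteny`, `ct`; plus `truth`
#'   (list) and `config`.
#' @export
simulate_family <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "vq_sim_config"))
  set.seed(cfg$seed)
  chroms <- sprintf("C%02d", seq_len(cfg$n_chromosomes))
  copy_levels <- as.integer(names(cfg$copy_distribution))
  types <- names(cfg$motif_type_distribution)
  sub_labels <- c("LF", "MF1", "MF2")

  genes <- list(); proteins <- list(); synteny <- list()
  truth_genes <- list(); tandem_pairs <- list()

  for (l in seq_len(cfg$n_ref_loci)) {
    copies <- copy_levels[sample.int(length(copy_levels), 1L,
                                     prob = cfg$copy_distribution)]
    type <- types[sample.int(length(types), 1L,
                             prob = cfg$motif_type_distribution)]
    len <- sample(seq(cfg$protein_length_range[1],
                      cfg$protein_length_range[2]), 1L)
    anc <- plant_motif_protein(len, type)
    ref_locus <- sprintf("RefVQ%d (REF%03d)", l, l)
    is_tandem_locus <- copies >= 2L && runif(1) < cfg$tandem_fraction
    locus_chroms <- sample(chroms, copies)   # distinct chromosomes
    gene_len <- 3L * (len + 1L)
    tandem_start <- NA_real_
    for (ci in seq_len(copies)) {
      gname <- if (copies == 1L) sprintf("SynVQ%d", l) else
        sprintf("SynVQ%d-%d", l, ci)
      seq_i <- if (ci == 1L) anc$sequence else
        mutate_copy(anc$sequence, cfg$substitution_rate, anc$motif_start,
                    cfg$protect_motif, type)
      if (is_tandem_locus && ci == 2L) {
        chrom <- genes[[length(genes)]]$chrom
        gap <- sample(500:5000, 1L)
        start <- genes[[length(genes)]]$end + gap + 1L
      } else {
        chrom <- locus_chroms[ci]
        start <- sample.int(cfg$chromosome_length - gene_len - 20000L, 1L)
      }
      end <- start + gene_len - 1L
      if (end > cfg$chromosome_length) vq_abort("infeasible placement")
      genes[[length(genes) + 1L]] <- tibble(
        gene_name = gname, locus_id = sprintf("SYN%03d%d", l, ci),
        chrom = chrom, strand = sample(c("+", "-"), 1L),
        start = start, end = end, cds_length = gene_len
      )
      proteins[[length(proteins) + 1L]] <- tibble(id = gname,
                                                  sequence = seq_i)
      synteny[[length(synteny) + 1L]] <- tibble(
        block = "S", tpck_chrom = "tPCK1", ref_locus = ref_locus,
        gene_name = gname, subgenome = if (copies == 1L)
          sample(sub_labels, 1L) else sub_labels[ci]
      )
      truth_genes[[length(truth_genes) + 1L]] <- tibble(
        gene_name = gname, ref_locus = ref_locus, copy = ci,
        copies = copies, motif_type = type,
        tandem = is_tandem_locus && ci <= 2L
      )
    }
    if (is_tandem_locus) {
      gs <- sort(vapply(tail(truth_genes, copies)[1:2],
                        function(x) x$gene_name, character(1)))
      tandem_pairs[[length(tandem_pairs) + 1L]] <-
        tibble(gene_a = gs[1], gene_b = gs[2])
    }
  }
  genes <- bind_rows(genes)
  proteins <- bind_rows(proteins)
  synteny <- bind_rows(synteny) %>%
    mutate(group_id = .data$ref_locus)
  truth_genes <- bind_rows(truth_genes)

  # plant introns into a few genes: split the CDS into k+1 exons and
  # widen the genomic span by the intron total
  genes$exons <- purrr::map2(genes$start, genes$end,
                             ~ cbind(start = .x, end = .y))
  intron_counts <- setNames(rep(0L, nrow(genes)), genes$gene_name)
  if (cfg$n_intron_genes > 0L) {
    picked <- sample.int(nrow(genes), min(cfg$n_intron_genes, nrow(genes)))
    for (gi in picked) {
      k <- sample(1:3, 1L)
      cds_len <- genes$cds_length[gi]
      cuts <- sort(sample(seq(3L, cds_len - 3L, by = 3L), k))
      intron_lens <- sample(100:500, k, replace = TRUE)
      ex_start <- genes$start[gi]
      exons <- matrix(0L, k + 1L, 2L,
                      dimnames = list(NULL, c("start", "end")))
      prev_cut <- 0L
      for (e in seq_len(k + 1L)) {
        this_cut <- if (e <= k) cuts[e] else cds_len
        exons[e, ] <- c(ex_start, ex_start + (this_cut - prev_cut) - 1L)
        if (e <= k) ex_start <- exons[e, 2L] + intron_lens[e] + 1L
        prev_cut <- this_cut
      }
      genes$exons[[gi]] <- exons
      genes$end[gi] <- exons[k + 1L, 2L]
      intron_counts[gi] <- k
    }
  }

  cds <- tibble(id = proteins$id,
                sequence = vapply(proteins$sequence, back_translate,
                                  character(1), USE.NAMES = FALSE))

  # qPCR design: planted log2 fold changes per gene x non-calibrator cell
  cells <- tidyr::expand_grid(condition = cfg$conditions,
                              timepoint = cfg$timepoints)
  design <- tidyr::expand_grid(gene = genes$gene_name, cells) %>%
    mutate(is_calibrator = .data$condition == cfg$conditions[1] &
             .data$timepoint == cfg$timepoints[1],
           lfc = ifelse(.data$is_calibrator, 0,
                        sample(cfg$lfc_values, n(), replace = TRUE)))
  baseline <- setNames(runif(nrow(genes), 2, 8), genes$gene_name)
  ct <- design %>%
    tidyr::expand_grid(replicate = seq_len(cfg$n_replicates)) %>%
    mutate(
      ct_reference = rnorm(n(), 20, 0.15),
      ct_target = .data$ct_reference + baseline[.data$gene] - .data$lfc +
        rnorm(n(), 0, cfg$noise_sd)
    ) %>%
    select("gene", "condition", "timepoint", "replicate",
           "ct_target", "ct_reference")

  truth <- list(
    genes = truth_genes %>%
      mutate(intron_count = unname(intron_counts[.data$gene_name])),
    motif_census = truth_genes %>% count(.data$motif_type, name = "n") %>%
      rename(type_code = "motif_type") %>% arrange(desc(.data$n)),
    n_intronless = sum(intron_counts == 0L),
    n_genes = nrow(genes),
    tandem_pairs = if (length(tandem_pairs) > 0L) bind_rows(tandem_pairs)
      else tibble(gene_a = character(), gene_b = character()),
    chromosome_counts = genes %>% count(.data$chrom, name = "n"),
    subgenome_counts = synteny %>% count(.data$subgenome, name = "n"),
    expression = design
  )
  structure(list(proteins = proteins, cds = cds, genes = genes,
                 synteny = synteny, ct = ct, truth = truth, config = cfg),
            class = "vq_simulation")
}

#' Write a simulation to disk in standard formats
#'
#' Emits protein and CDS FASTA, GFF3, the gene/synteny/Ct TSV tables and
#' `truth.json` into a directory; every file is re-readable with the
#' package's own readers.
#'
#' @param sim a [simulate_family()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "vq_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(sim$proteins, file.path(dir, "proteins.faa"))
  write_fasta(sim$cds, file.path(dir, "cds.fna"))
  g <- sim$genes %>% mutate(location = paste0(.data$start, "-", .data$end))
  readr::write_tsv(g %>% select("gene_name", "locus_id", "chrom", "strand",
                                "location", "cds_length"),
                   file.path(dir, "gene_table.tsv"))
  readr::write_tsv(sim$synteny %>% select(-"group_id"),
                   file.path(dir, "synteny.tsv"))
  readr::write_tsv(sim$ct, file.path(dir, "ct_table.tsv"))
  gff <- c("##gff-version 3")
  for (i in seq_len(nrow(sim$genes))) {
    r <- sim$genes[i, ]
    ex <- r$exons[[1]]
    gff <- c(
      gff,
      sprintf("%s\tvqfam\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              r$chrom, r$start, r$end, r$strand, r$locus_id),
      sprintf("%s\tvqfam\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              r$chrom, r$start, r$end, r$strand, r$gene_name, r$locus_id),
      sprintf("%s\tvqfam\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s",
              r$chrom, ex[, "start"], ex[, "end"], r$strand,
              r$gene_name, r$gene_name)
    )
  }
  writeLines(gff, file.path(dir, "genes.gff3"))
  truth <- sim$truth
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' Synthetic stand-in proteome with exact planted motif-type counts
#'
#' Builds a proteome with exactly the requested number of proteins per
#' motif type (each carrying one strict VQ window of that type), with
#' lengths drawn uniformly from `length_range`. This is a synthetic
#' stand-in used where a real proteome is unavailable; the planted counts
#' are the ground truth a scanner must recover.
#'
#' @param type_counts named integer vector, e.g.
#'   `c(LTG = 43, FTG = 8, VTG = 3, LTS = 1, LTV = 1, YTG = 1)`.
#' @param length_range min/max protein length (aa).
#' @param seed integer RNG seed.
#' @param prefix id prefix.
#' @return a tibble with columns `id`, `sequence`, `type_code`.
#' @export
synthetic_proteome <- function(type_counts, length_range = c(93L, 568L),
                               seed = 1L, prefix = "SYNP") {
  set.seed(seed)
  types <- rep(names(type_counts), type_counts)
  rows <- purrr::imap(types, function(tp, i) {
    len <- sample(seq(length_range[1], length_range[2]), 1L)
    p <- plant_motif_protein(len, tp)
    tibble(id = sprintf("%s%03d", prefix, i), sequence = p$sequence,
           type_code = tp)
  })
  bind_rows(rows)
}
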