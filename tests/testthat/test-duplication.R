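test_that("ortholog naming suffixes by similarity with locus-id ties", {
  set.seed(51)
  refA <- random_aa(120)
  refB <- random_aa(120)
  mutate_at <- function(s, k) {
    aa <- strsplit(s, "")[[1]]
    idx <- sample(length(aa), k)
    aa[idx] <- vapply(aa[idx], function(x) sample(setdiff(aa20, x), 1),
                      character(1))
    paste(aa, collapse = "")
  }
  br <- tibble::tibble(
    id = c("Bra003", "Bra001", "Bra002", "Bra009"),
    sequence = c(mutate_at(refA, 30), mutate_at(refA, 5),
                 mutate_at(refA, 15), mutate_at(refB, 4))
  )
  ref <- tibble::tibble(id = c("AtVQ23", "AtVQ4"), sequence = c(refA, refB))
  got <- assign_names(br, ref)
  expect_equal(got$assigned_name[got$br_gene == "Bra001"], "BrVQ23-1")
  expect_equal(got$assigned_name[got$br_gene == "Bra002"], "BrVQ23-2")
  expect_equal(got$assigned_name[got$br_gene == "Bra003"], "BrVQ23-3")
  expect_equal(got$assigned_name[got$br_gene == "Bra009"], "BrVQ4")

  # identical copies: suffix order falls back to locus id
  br2 <- tibble::tibble(id = c("Bra200", "Bra100"), sequence = rep(refA, 2))
  got2 <- assign_names(br2, ref)
  expect_equal(got2$assigned_name[got2$br_gene == "Bra100"], "BrVQ23-1")
  expect_equal(got2$assigned_name[got2$br_gene == "Bra200"], "BrVQ23-2")
  expect_error(assign_names(br2[0, ], ref), "empty proteome")
})

test_that("chromosome census matches the printed distribution", {
  cc <- chromosome_census(table1_fixture())
  counts <- setNames(cc$n, cc$chrom)
  expect_equal(counts[c("A04", "A07", "A01", "A02", "A03", "A09",
                        "A05", "A06", "A08", "A10")],
               c(A04 = 8L, A07 = 8L, A01 = 7L, A02 = 7L, A03 = 6L,
                 A09 = 6L, A05 = 5L, A06 = 4L, A08 = 4L, A10 = 1L))
  expect_true(cc$is_scaffold[cc$chrom == "Scaffold000402"])
  expect_equal(sum(cc$n), 57L)
})

test_that("tandem requires same chromosome and a small gap", {
  dup <- classify_duplications(table2_fixture(), table1_fixture())
  tp <- dup$pairs[dup$pairs$mode == "tandem", ]
  expect_equal(nrow(tp), 1L)
  expect_equal(sort(c(tp$gene_a, tp$gene_b)), c("BrVQ23-2", "BrVQ23-3"))
  expect_lt(tp$gap_bp, 25000)
  # same chromosome but megabases apart stays segmental
  seg_1023 <- dup$pairs[dup$pairs$gene_a == "BrVQ10-2" &
                          dup$pairs$gene_b == "BrVQ10-3", ]
  expect_equal(seg_1023$mode, "segmental")
  expect_equal(seg_1023$chrom_a, seg_1023$chrom_b)
  expect_equal(dup$summary$n_segmental_genes, 41L)
})

test_that("duplication labels ignore member order and need coordinates", {
  s <- table2_fixture()
  g <- table1_fixture()
  a <- classify_duplications(s, g)
  set.seed(52)
  b <- classify_duplications(s[sample(nrow(s)), ], g[sample(nrow(g)), ])
  expect_equal(dplyr::arrange(tidy(a), gene_name),
               dplyr::arrange(tidy(b), gene_name))
  expect_error(classify_duplications(s, g[g$gene_name != "BrVQ23-2", ]),
               "BrVQ23-2")
})

test_that("planted duplication modes are recovered across gap thresholds", {
  sim <- simulate_family(simulation_config(seed = 53, n_ref_loci = 12,
                                           tandem_fraction = 0.5))
  truth_tandem <- sim$truth$genes$gene_name[sim$truth$genes$tandem]
  # planted tandem gaps are < 5 kb + gene length; planted segmental pairs
  # sit on different chromosomes, so any threshold in between is exact
  for (gap in c(6000, 25000)) {
    dup <- classify_duplications(sim$synteny, sim$genes, tandem_max_gap = gap)
    got <- tidy(dup)
    expect_equal(sort(got$gene_name[got$label == "tandem"]),
                 sort(truth_tandem))
  }
  sim0 <- simulate_family(simulation_config(seed = 54, n_ref_loci = 12,
                                            tandem_fraction = 0))
  dup0 <- classify_duplications(sim0$synteny, sim0$genes)
  expect_equal(dup0$summary$n_tandem_pairs, 0L)
})

test_that("subgenome tabulation counts members and copy classes", {
  tab <- subgenome_tabulate(table2_fixture())
  expect_equal(setNames(tab$subgenome_counts$n, tab$subgenome_counts$subgenome),
               c(LF = 21L, MF1 = 23L, MF2 = 12L))
  expect_equal(tab$copy_histogram$n_loci[tab$copy_histogram$copies == 3], 7L)
  expect_equal(tab$n_anchored_loci, 28L)
  expect_equal(tab$n_member_genes, 56L)

  one <- tibble::tibble(block = "E", tpck_chrom = "tPCK6",
                        ref_locus = "RefX", gene_name = c("g1", "g2"),
                        subgenome = c("LF", "LF"))
  t1 <- subgenome_tabulate(one)
  expect_equal(t1$subgenome_counts$n, 2L)
  expect_equal(t1$copy_histogram,
               tibble::tibble(copies = 2L, n_loci = 1L))
  bad <- dplyr::mutate(one, subgenome = c("LF", "QQ"))
  expect_error(subgenome_tabulate(bad), "unknown subgenome")
})
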