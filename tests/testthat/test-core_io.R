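test_that("FASTA reader parses, folds lines and validates", {
  f <- write_tmp(c(">a", "MKV"), ".faa")
  expect_equal(read_fasta(f), tibble::tibble(id = "a", sequence = "MKV"))

  f <- write_tmp(c(">a desc text", "MK", "VQ", ">b", "FF"), ".faa")
  got <- read_fasta(f)
  expect_equal(got$id, c("a", "b"))
  expect_equal(got$sequence, c("MKVQ", "FF"))

  expect_error(read_fasta(write_tmp(character(0))), "no records")
  expect_error(read_fasta(write_tmp(c(">a", "MK", ">a", "VV"))),
               "duplicate id: a")
  expect_error(read_fasta(write_tmp(c(">a", "MK", "M7K"))),
               "illegal character '7' at line 3")
})

test_that("FASTA writer is the reader's inverse on random records", {
  set.seed(11)
  for (rep in 1:10) {
    recs <- tibble::tibble(
      id = paste0("s", 1:5),
      sequence = vapply(sample(10:200, 5), random_aa, character(1))
    )
    f <- tempfile(fileext = ".faa")
    write_fasta(recs, f, width = 17)
    expect_equal(read_fasta(f), recs)
  }
})

test_that("gene table parser handles printed location formats", {
  hdr <- "gene_name\tlocus_id\tchrom\tstrand\tlocation\tcds_length"
  f <- write_tmp(c(hdr,
                   "BrVQ1-1\tBra025998\tA06\t-\t6,588,703–6,588,999\t297"))
  g <- read_gene_table(f)
  expect_equal(g$start, 6588703L)
  expect_equal(g$end, 6588999L)
  expect_equal(g$cds_length, 297L)
  expect_equal(g$end - g$start + 1L, g$cds_length)

  # misplaced thousands separators as printed
  f <- write_tmp(c(hdr, "BrVQ8\tBra033934\tA02\t-\t108,00,121-10,800,534\t414"))
  g <- read_gene_table(f)
  expect_equal(c(g$start, g$end), c(10800121L, 10800534L))

  # span may legitimately exceed the CDS (introns)
  f <- write_tmp(c(hdr, "BrVQ35\tBra006328\tA03\t-\t3,034,196-3,038,533\t1707"))
  g <- read_gene_table(f)
  expect_equal(g$end - g$start + 1L, 4338L)

  expect_error(read_gene_table(
    write_tmp(c(hdr, "x\ty\tA01\t+\t10-5\t297"))), "start > end")
  expect_warning(read_gene_table(
    write_tmp(c(hdr, "x\ty\tA01\t+\t1-100\t100"))), "multiple of 3")
})

test_that("packaged family table satisfies the span/CDS relation", {
  g <- table1_fixture()
  expect_equal(nrow(g), 57L)
  expect_true(all(g$end - g$start + 1L >= g$cds_length))
  expect_equal(g$chrom[g$gene_name == "BrVQ22-2"], "Scaffold000402")
  expect_equal(g$cds_length[g$gene_name == "BrVQ10-3"], 282L)
})

test_that("GFF3 reader builds exon structure and checks linkage", {
  gff <- c("##gff-version 3",
           "chr1\t.\tgene\t101\t400\t.\t+\t.\tID=g1",
           "chr1\t.\tmRNA\t101\t400\t.\t+\t.\tID=m1;Parent=g1",
           "chr1\t.\tCDS\t101\t400\t.\t+\t0\tID=c1;Parent=m1")
  g <- read_gff3(write_tmp(gff, ".gff3"))
  expect_equal(g$cds_length, 300L)
  expect_equal(nrow(g$exons[[1]]), 1L)

  gff2 <- c("##gff-version 3",
            "chr1\t.\tgene\t101\t400\t.\t+\t.\tID=g1",
            "chr1\t.\tmRNA\t101\t400\t.\t+\t.\tID=m1;Parent=g1",
            "chr1\t.\tCDS\t101\t200\t.\t+\t0\tID=c1;Parent=m1",
            "chr1\t.\tCDS\t301\t400\t.\t+\t0\tID=c2;Parent=m1")
  g2 <- read_gff3(write_tmp(gff2, ".gff3"))
  expect_equal(g2$cds_length, 200L)
  expect_equal(intron_count(g2)$intron_count, 1L)

  gff3 <- c("##gff-version 3",
            "chr1\t.\tmRNA\t101\t400\t.\t+\t.\tID=m1",
            "chr1\t.\tCDS\t101\t200\t.\t+\t0\tID=c1")
  expect_error(read_gff3(write_tmp(gff3, ".gff3")), "Parent")

  gff4 <- c("##gff-version 3",
            "chr1\t.\tmRNA\t101\t400\t.\t+\t.\tID=m1",
            "chr1\t.\tCDS\t101\t250\t.\t+\t0\tID=c1;Parent=m1",
            "chr1\t.\tCDS\t200\t400\t.\t+\t0\tID=c2;Parent=m1")
  expect_error(read_gff3(write_tmp(gff4, ".gff3")), "overlapping")
})

test_that("newick round trip preserves topology, lengths and supports", {
  t1 <- read_newick("(A:1,B:1,C:3);")
  expect_equal(sort(t1$tip.label), c("A", "B", "C"))
  expect_equal(read_newick(write_newick(t1))$edge.length, t1$edge.length)

  t2 <- read_newick("((A:1,B:1)95:0.5,C:1);")
  expect_true("95" %in% t2$node.label)
  rt <- read_newick(write_newick(t2))
  expect_true("95" %in% rt$node.label)

  expect_error(read_newick("((A,B"), "unbalanced parentheses")

  set.seed(7)
  for (rep in 1:5) {
    tr <- ape::rtree(8)
    rt <- read_newick(write_newick(tr))
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(rt))[1], 0)
    expect_equal(sort(rt$edge.length), sort(tr$edge.length),
                 tolerance = 1e-6)
  }
})

test_that("synteny and ct readers validate labels and values", {
  s <- table2_fixture()
  expect_equal(nrow(s), 56L)
  expect_equal(dplyr::n_distinct(s$gene_name), 56L)
  expect_error(read_synteny_table(write_tmp(c(
    "block\ttpck_chrom\tref_locus\tgene_name\tsubgenome",
    "A\ttPCK1\tX1\tg1\tZZ"))), "unknown subgenome")
  expect_error(read_ct_table(write_tmp(c(
    "gene\tcondition\ttimepoint\treplicate\tct_target\tct_reference",
    "g1\tCK\t0h\t1\t-3\t20"))), "finite and > 0")
})
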