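test_that("pairwise alignment reports identity and similarity", {
  expect_equal(global_align("MKVQ", "MKVQ")$identity_pct, 100)
  expect_equal(global_align("AAAA", "AACA")$identity_pct, 75)
  expect_error(global_align("", "MK"), "empty sequence")
  # conservative substitution scores positively -> similarity > identity
  pa <- global_align("MKVLD", "MKILE")
  expect_gt(pa$similarity_pct, pa$identity_pct)
})

test_that("progressive MSA reduces to pairwise and keeps identicals gap-free", {
  two <- tibble::tibble(id = c("x", "y"), sequence = c("MKVQW", "MKQW"))
  m2 <- progressive_msa(two)
  pa <- global_align("MKVQW", "MKQW")
  expect_equal(m2$alignment$aligned, pa$alignment$aligned)

  three <- tibble::tibble(id = c("a", "b", "c"),
                          sequence = rep("MKVQWERTY", 3))
  m3 <- progressive_msa(three)
  expect_false(any(grepl("-", m3$alignment$aligned, fixed = TRUE)))
  expect_error(progressive_msa(three[1, ]), "at least 2")
})

test_that("a planted insertion aligns as one gap block in other rows", {
  set.seed(41)
  base <- random_aa(60)
  ins <- paste0(substr(base, 1, 30), "WWHWWH", substr(base, 31, 60))
  fam <- tibble::tibble(id = c("s1", "s2", "s3", "s4"),
                        sequence = c(base, base, ins, base))
  m <- progressive_msa(fam)
  expect_equal(m$n_columns, 66)
  gapped <- m$alignment$aligned[m$alignment$id != "s3"]
  expect_true(all(grepl("-{6}", gapped)))
  expect_false(grepl("-", m$alignment$aligned[m$alignment$id == "s3"]))
})

test_that("distance models match closed forms", {
  al <- tibble::tibble(id = c("a", "b"), aligned = c("MKVQ", "MKVQ"))
  expect_equal(distance_matrix(al)["a", "b"], 0)
  al2 <- tibble::tibble(id = c("a", "b"), aligned = c("MKVQ", "MKVA"))
  expect_equal(distance_matrix(al2)["a", "b"], 0.25)
  expect_equal(distance_matrix(al2, model = "poisson")["a", "b"],
               -log(0.75), tolerance = 1e-10)
  al3 <- tibble::tibble(id = c("a", "b"), aligned = c("MK--", "--VQ"))
  expect_error(distance_matrix(al3), "no valid columns")
  al4 <- tibble::tibble(id = c("a", "b"), aligned = c("MKVQ", "WRDE"))
  expect_error(distance_matrix(al4, model = "poisson"), "infinite Poisson")
})

test_that("three-taxon NJ solves the branch equations", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  got <- tree_distances(tr)
  expect_equal(got[rownames(d), colnames(d)], d)
  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
})

test_that("NJ inverts additive matrices from random binary trees", {
  set.seed(42)
  for (n in c(4, 6, 8, 10, 12)) {
    for (rep in 1:3) {
      tr <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
      d <- tree_distances(tr)
      est <- nj_tree(d)
      expect_equal(sort(est$tip.label), sort(tr$tip.label))
      # path lengths reproduce the matrix exactly (additivity)
      got <- tree_distances(est)[rownames(d), colnames(d)]
      expect_equal(got, d, tolerance = 1e-6)
      # topology agrees with the independent NJ implementation
      ref <- ape::nj(d)
      expect_equal(ape::dist.topo(ape::unroot(est), ape::unroot(ref))[1], 0)
    }
  }
})

test_that("bootstrap gives full support to trivially split taxa", {
  al <- tibble::tibble(
    id = c("a1", "a2", "b1", "b2"),
    aligned = c(strrep("A", 40), strrep("A", 40),
                strrep("W", 40), strrep("W", 40))
  )
  bt <- bootstrap_tree(al, n_reps = 100, seed = 3)
  sup <- suppressWarnings(as.numeric(bt$node.label))
  expect_true(all(sup[!is.na(sup)] == 100))
  expect_error(bootstrap_tree(al, n_reps = 0, seed = 1), "n_reps")
  expect_error(bootstrap_tree(
    tibble::tibble(id = c("a", "b"), aligned = c("A", "C")),
    n_reps = 2, seed = 1), "fewer than 2")
})

test_that("bootstrap is reproducible and supports planted clades", {
  set.seed(44)
  cores <- replicate(4, random_aa(40))
  fam <- tibble::tibble(
    id = sprintf("t%02d", 1:8),
    sequence = vapply(rep(1:4, each = 2), function(k) {
      aa <- strsplit(cores[k], "")[[1]]
      idx <- sample(40, 3)
      aa[idx] <- sample(aa20, 3, TRUE)
      paste(aa, collapse = "")
    }, character(1))
  )
  m <- progressive_msa(fam)
  bt1 <- bootstrap_tree(m, n_reps = 200, seed = 5)
  bt2 <- bootstrap_tree(m, n_reps = 200, seed = 5)
  expect_identical(write_newick(bt1), write_newick(bt2))
  # each planted pair is a clade with strong support
  sp <- vqfam:::tree_splits(bt1)
  sup <- setNames(bt1$node.label,
                  names(sp))
  for (k in 1:4) {
    key <- paste(sort(fam$id[(2 * k - 1):(2 * k)]), collapse = "|")
    node <- names(sp)[!is.na(sp) & sp == key]
    if (length(node) == 1L) {
      expect_gte(as.numeric(sup[[node]]), 70)
    }
  }
})

test_that("cutting k-1 long edges recovers planted groups", {
  nwk <- paste0("(",
                paste(vapply(1:7, function(k) {
                  sprintf("(g%da:0.05,g%db:0.05):1.0", k, k)
                }, character(1)), collapse = ","), ");")
  tr <- read_newick(nwk)
  one <- cut_subgroups(tr, 1)
  expect_equal(dplyr::n_distinct(one$group), 1L)
  all_single <- cut_subgroups(tr, length(tr$tip.label))
  expect_equal(dplyr::n_distinct(all_single$group), length(tr$tip.label))
  seven <- cut_subgroups(tr, 7)
  expect_equal(dplyr::n_distinct(seven$group), 7L)
  planted <- sub("[ab]$", "", seven$id)
  expect_equal(dplyr::n_distinct(paste(planted, seven$group)), 7L)
  expect_error(cut_subgroups(tr, 99), "between 1")
})
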