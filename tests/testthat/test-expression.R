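# build a replicate-level Ct table with known dCt means per cell
make_ct <- function(dct_by_cell, n = 3, sd = 0.1, seed = 1) {
  set.seed(seed)
  purrr::pmap(dct_by_cell, function(gene, condition, timepoint, dct) {
    tibble::tibble(
      gene = gene, condition = condition, timepoint = timepoint,
      replicate = seq_len(n),
      ct_reference = rnorm(n, 20, 0.1)
    ) %>% dplyr::mutate(ct_target = ct_reference + dct + rnorm(n, 0, sd))
  }) %>% dplyr::bind_rows()
}

test_that("dCt / ddCt / rq closed forms", {
  expect_equal(delta_ct(25, 20), 5)
  expect_equal(delta_ct(18.5, 20.25), -1.75)
  rq <- relative_quantification(5, 8)
  expect_equal(rq$ddct, -3)
  expect_equal(rq$rq, 8)
  expect_equal(relative_quantification(6, 5)$rq, 0.5)
  expect_equal(relative_quantification(4, 4)$rq, 1)
})

test_that("calibrator cells have rq exactly 1", {
  cells <- tidyr::expand_grid(gene = c("g1", "g2"),
                              condition = c("CK", "T"),
                              timepoint = "0h") %>%
    dplyr::mutate(dct = c(3, 3.5, 4, 1))
  ex <- analyze_expression(make_ct(cells), "CK:0h")
  expect_equal(ex$rq[ex$is_calibrator], c(1, 1))
  expect_equal(ex$call[ex$is_calibrator], rep("calibrator", 2))
})

test_that("negating all dCt inverts rq exactly", {
  cells <- tidyr::expand_grid(gene = "g1", condition = c("CK", "T"),
                              timepoint = "0h") %>%
    dplyr::mutate(dct = c(2, 5))
  ct <- make_ct(cells, seed = 3)
  ex <- analyze_expression(ct, "CK:0h")
  swapped <- dplyr::rename(ct, ct_target = "ct_reference",
                           ct_reference = "ct_target")
  ex2 <- analyze_expression(swapped, "CK:0h")
  expect_equal(ex2$rq, 1 / ex$rq, tolerance = 1e-12)
})

test_that("a planted 8-fold induction is called up", {
  cells <- tidyr::expand_grid(gene = "g1", condition = c("CK", "PEG"),
                              timepoint = "3h") %>%
    dplyr::mutate(dct = c(6, 3))    # ddCt = -3 -> 8-fold
  ex <- analyze_expression(make_ct(cells, sd = 0.1, seed = 7), "CK:3h")
  hit <- ex[!ex$is_calibrator, ]
  expect_equal(hit$call, "up")
  expect_gt(hit$rq, 6); expect_lt(hit$rq, 10)
  expect_true(hit$stars %in% c("*", "**"))
})

test_that("significance without fold change stays ns", {
  cells <- tidyr::expand_grid(gene = "g1", condition = c("CK", "T"),
                              timepoint = "0h") %>%
    dplyr::mutate(dct = c(5, 5 - log2(1.5)))   # rq ~ 1.5
  ex <- analyze_expression(make_ct(cells, n = 8, sd = 0.02, seed = 11),
                           "CK:0h")
  hit <- ex[!ex$is_calibrator, ]
  expect_lt(hit$p_value, 0.05)
  expect_equal(hit$call, "ns")
})

test_that("null simulations rarely produce calls (type-I control)", {
  calls <- vapply(1:100, function(s) {
    cells <- tidyr::expand_grid(gene = "g1", condition = c("CK", "T"),
                                timepoint = "0h") %>%
      dplyr::mutate(dct = c(4, 4))
    ex <- analyze_expression(make_ct(cells, sd = 0.2, seed = 1000 + s),
                             "CK:0h")
    ex$call[!ex$is_calibrator]
  }, character(1))
  expect_gte(mean(calls == "ns"), 0.9)
})

test_that("log2 fold-change estimates are unbiased at planted effects", {
  set.seed(61)
  lfc <- sample(-3:3, 200, replace = TRUE)
  est <- vapply(seq_along(lfc), function(i) {
    cal <- rnorm(3, 5, 0.2)
    smp <- rnorm(3, 5 - lfc[i], 0.2)
    -(mean(smp) - mean(cal))
  }, numeric(1))
  bias <- mean(est - lfc)
  # Monte-Carlo standard error of the mean bias at n=3, sd=0.2
  mc_se <- 0.2 * sqrt(2 / 3) / sqrt(200)
  expect_lt(abs(bias), 4 * mc_se)
})

test_that("degenerate designs are handled explicitly", {
  cells <- tidyr::expand_grid(gene = "g1", condition = c("CK", "T"),
                              timepoint = "0h") %>%
    dplyr::mutate(dct = c(3, 1))
  ct1 <- make_ct(cells, n = 1, seed = 13)
  ex1 <- analyze_expression(ct1, "CK:0h")
  hit <- ex1[!ex1$is_calibrator, ]
  expect_true(is.na(hit$p_value))
  expect_true(is.na(hit$call))
  expect_gt(hit$rq, 1)
  expect_error(analyze_expression(ct1, "CK:24h"), "missing calibrator")
})

test_that("log2 report transforms and flags wide dynamic ranges", {
  df <- tibble::tibble(gene = c("g", "g", "h", "h"),
                       rq = c(1, 8, 0.25, 1))
  out <- log2_report(df, range_threshold = 6)
  expect_equal(out$log2_rq, c(0, 3, -2, 0))
  expect_equal(out$log_display, c(TRUE, TRUE, FALSE, FALSE))
  expect_error(log2_report(tibble::tibble(gene = "g", rq = 0)), "positive")
})
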