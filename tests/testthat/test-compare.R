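test_that("standardized levels are median within-sample z-scores", {
  m <- matrix(c(2, 0, 2, 0), 2, 2,
              dimnames = list(c("A", "B"), c("s1", "s2")))
  sl <- standardized_level(matrix_to_expr(m), site = "x")
  expect_equal(sl$value[sl$gene_id == "A"], 1 / sqrt(2))
  expect_equal(sl$value[sl$gene_id == "B"], -1 / sqrt(2))
  # adding a constant within a sample changes nothing
  m2 <- m
  m2[, 1] <- m2[, 1] + 100
  sl2 <- standardized_level(matrix_to_expr(m2))
  expect_equal(sl2$value, sl$value)
  # a gene at the sample mean scores zero
  m3 <- matrix(c(1, 2, 3), 3, 1, dimnames = list(c("a", "b", "c"), "s1"))
  expect_equal(standardized_level(matrix_to_expr(m3))$value[2], 0)
})

test_that("detection overlap partitions the gene sets", {
  ov <- detection_overlap(c("g1", "g2", "g3"), c("g2", "g3", "g4"))
  expect_setequal(ov$both, c("g2", "g3"))
  expect_setequal(ov$only_a, "g1")
  expect_setequal(ov$only_b, "g4")
  expect_equal(unname(ov$counts[1:3]), c(2L, 1L, 1L))
  expect_length(detection_overlap(c("g1", "g2"), c("g1"))$only_b, 0)
  empty <- detection_overlap(c("g1"), character(0))
  expect_length(empty$both, 0)
})

test_that("Welch test matches the textbook oracle", {
  same <- welch_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  hi <- welch_test(c(10, 11, 12), c(1, 2, 3))
  expect_lt(hi$p, 0.01)
  withr::local_seed(15)
  for (rep in 1:100) {
    a <- rnorm(sample(3:10, 1))
    b <- rnorm(sample(3:10, 1), sd = runif(1, 0.5, 2))
    got <- welch_test(a, b)
    want <- oracle_welch(a, b)
    expect_equal(got$t, want$t, tolerance = 1e-8)
    expect_equal(got$df, want$df, tolerance = 1e-8)
    expect_equal(got$p, want$p, tolerance = 1e-8)
  }
})

test_that("one-tailed t tests handle paired and degenerate input", {
  got <- paired_unpaired_ttests(c(2, 4, 6, 8), c(1, 2, 3, 4),
                                paired = TRUE)
  want <- oracle_paired_t(c(2, 4, 6, 8), c(1, 2, 3, 4))
  expect_equal(got$t, want$t, tolerance = 1e-10)
  expect_equal(got$t, 3.873, tolerance = 1e-3)
  expect_equal(got$p, want$p, tolerance = 1e-10)
  expect_equal(got$p, 0.0152, tolerance = 5e-3)
  eq <- paired_unpaired_ttests(c(1, 2, 3), c(1, 2, 3))
  expect_equal(eq$p, 0.5)
  expect_error(
    paired_unpaired_ttests(c(2, 3, 4, 5), c(1, 2, 3, 4), paired = TRUE),
    "identical"
  )
  expect_error(
    paired_unpaired_ttests(c(1, 2), c(1, 2, 3), paired = TRUE),
    "length"
  )
})

test_that("Fisher's exact test matches enumeration", {
  expect_equal(fisher_habitat_test(matrix(c(2, 1, 1, 2), 2, 2))$p, 1)
  expect_equal(fisher_habitat_test(matrix(c(5, 0, 0, 5), 2, 2))$p,
               2 / 252, tolerance = 1e-12)
  withr::local_seed(16)
  for (rep in 1:20) {
    tab <- matrix(sample(0:8, 4, replace = TRUE), 2, 2)
    if (sum(tab) == 0 || any(rowSums(tab) == 0) ||
        any(colSums(tab) == 0)) next
    expect_equal(fisher_habitat_test(tab)$p, oracle_fisher_p(tab),
                 tolerance = 1e-10)
  }
  expect_error(fisher_habitat_test(matrix(c(1.5, 1, 1, 1), 2, 2)))
})

test_that("correlations match the rank oracle and handle ties", {
  x <- 1:6
  expect_equal(correlations(x, x, "pearson")$rho, 1)
  expect_equal(correlations(x, x, "spearman")$rho, 1)
  expect_equal(correlations(x, rev(x), "spearman")$rho, -1)
  y <- c(2, 2, 3, 5, 4, 6)  # one tie
  expect_equal(correlations(x, y, "spearman")$rho,
               oracle_spearman(x, y), tolerance = 1e-10)
})

test_that("pathway medians correlate across sites per pathway", {
  ann <- tibble::tibble(gene_id = sprintf("g%02d", 1:12),
                        pathway = rep(c("P1", "P2"), each = 6))
  withr::local_seed(17)
  la <- tibble::tibble(gene_id = ann$gene_id, value = rnorm(12))
  lb <- tibble::tibble(gene_id = ann$gene_id,
                       value = la$value + rnorm(12, sd = 0.1))
  pc <- pathway_correlations(la, lb, ann, min_genes = 5)
  expect_equal(nrow(pc), 2)
  expect_true(all(pc$rho > 0.5))
  # below the gene minimum every pathway is dropped
  pc2 <- pathway_correlations(la[1:4, ], lb, ann, min_genes = 5)
  expect_equal(nrow(pc2), 0)
})

test_that("pathway quantile matrix follows the 5% grid rules", {
  mk_source <- function(levels, detected = TRUE, n_samples = 3) {
    tidyr::crossing(
      tibble::tibble(gene_id = names(levels), base = unname(levels)),
      sample_id = paste0("s", seq_len(n_samples))
    ) |>
      dplyr::mutate(level = base, detected = detected) |>
      dplyr::select(gene_id, sample_id, level, detected)
  }
  ann <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                        pathway = c("P1", "P2", "P3"))
  pm <- pathway_matrix(list(site = mk_source(c(g1 = 1, g2 = 5, g3 = 9))),
                       ann)
  expect_equal(sort(pm$matrix$site), c(0, 0.5, 1))
  # all pathways tied: mean rank gives 0.5 everywhere
  pm_tied <- pathway_matrix(list(site = mk_source(c(g1 = 2, g2 = 2,
                                                    g3 = 2))), ann)
  expect_true(all(pm_tied$matrix$site == 0.5))
  # detected in 3 of 10 samples is not more than one third: dropped
  src <- mk_source(c(g1 = 1, g2 = 5, g3 = 9), n_samples = 10) |>
    dplyr::mutate(detected = ifelse(gene_id == "g3",
                                    sample_id %in% c("s1", "s2", "s3"),
                                    TRUE))
  pm_drop <- pathway_matrix(list(site = src), ann)
  expect_false("P3" %in% pm_drop$matrix$pathway)
  expect_setequal(pm_drop$matrix$pathway, c("P1", "P2"))
  # quantiles are invariant to monotone transforms of the levels
  src_a <- mk_source(c(g1 = 1, g2 = 5, g3 = 9, g4 = 2))
  src_b <- src_a |> dplyr::mutate(level = exp(level))
  ann4 <- tibble::tibble(gene_id = paste0("g", 1:4),
                         pathway = paste0("P", 1:4))
  qa <- pathway_matrix(list(s = src_a), ann4)$matrix
  qb <- pathway_matrix(list(s = src_b), ann4)$matrix
  expect_equal(qa, qb)
})

test_that("peak shifts are minimal circular distances with categories", {
  pa <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                       peak_label = c("L9", "D6", "D12"))
  pb <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                       peak_label = c("L12", "L6", "D12"))
  ps <- peak_shift_table(pa, pb)
  expect_equal(ps$shift_hours, c(3, 12, 0))
  expect_equal(ps$category,
               c("shifted_lt6", "shifted_ge6", "maintained"))
  # symmetry and the 12 h bound
  ps_rev <- peak_shift_table(pb, pa)
  expect_equal(ps_rev$shift_hours, ps$shift_hours)
  withr::local_seed(18)
  a <- runif(50, 0, 24)
  b <- runif(50, 0, 24)
  expect_true(all(circular_shift(a, b) <= 12))
  expect_equal(circular_shift(a, b), circular_shift(b, a))
})
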