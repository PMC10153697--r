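test_that("noise floor uses the bottom decile with a two-gene minimum", {
  fl <- noise_floor(1:20)
  expect_equal(unname(fl["mu_noise"]), 1.5)
  expect_equal(unname(fl["sigma_noise"]), sd(c(1, 2)))
  expect_error(noise_floor(1:10), ">= 20")
  expect_error(noise_floor(c(rep(1, 3), 4:20)), "spread")
  # G = 30 at decile 0.10 uses floor(3.0) = 3 genes
  x <- c(1, 2, 3, rnorm(27, 10))
  fl30 <- noise_floor(x)
  expect_equal(unname(fl30["mu_noise"]), 2)
  expect_equal(unname(fl30["sigma_noise"]), sd(1:3))
})

test_that("SNR is a strict z-score threshold", {
  expect_equal(snr(1.5, 1.5, 0.7071), 0)
  expect_equal(snr(10, 1.5, sd(c(1, 2))), (10 - 1.5) / sd(c(1, 2)))
  fl <- c(mu_noise = 0, sigma_noise = 1)
  m <- matrix(c(5, 5.0001, rep(0, 38)), 20, 2,
              dimnames = list(paste0("g", 1:20), c("s1", "s2")))
  # build a column large enough for a floor: use detect_snr on 20 genes
  expr <- matrix_to_expr(matrix(c(seq(1, 20), seq(1, 20)), 20, 2,
                                dimnames = list(paste0("g", 1:20),
                                                c("s1", "s2"))))
  snr_tbl <- detect_snr(expr, threshold = 5)
  g20 <- dplyr::filter(snr_tbl, gene_id == "g20", sample_id == "s1")
  expect_equal(g20$snr, (20 - 1.5) / sd(c(1, 2)))
  # value sitting exactly at SNR 5 is not detected (strict >)
  at5 <- 1.5 + 5 * sd(c(1, 2))
  expr5 <- expr
  expr5$s1[20] <- at5
  t5 <- dplyr::filter(detect_snr(expr5, 5), gene_id == "g20",
                      sample_id == "s1")
  expect_false(t5$above_snr)
})

test_that("spike calibration is an exact line through collinear points", {
  design <- make_design(1, 3, 1, 6, 12)
  sp <- tibble::tibble(
    ercc_id = c("a", "b", "c"),
    concentration = 2^c(1, 2, 3),
    sample_id = "L3_r1",
    intensity = 2^c(4, 6, 8),
    is_min = c(TRUE, FALSE, FALSE)
  )
  fit <- fit_ercc_model(sp)
  expect_equal(fit$slope, 0.5, tolerance = 1e-12)
  expect_equal(fit$intercept, -1, tolerance = 1e-12)
  expect_equal(predict_log2_count(fit, 10), 4, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  expect_error(fit_ercc_model(sp[1:2, ]), ">= 3")
  flat <- dplyr::mutate(sp, intensity = 16)
  expect_error(fit_ercc_model(flat), "singular|constant")
})

# fixture: 20 genes x 10 samples with a controllable target gene
detect_fixture <- function(target_levels, spike_level = 6) {
  n_s <- length(target_levels)
  samples <- paste0("s", seq_len(n_s))
  m <- rbind(
    matrix(rep(seq(0.1, 2, length.out = 19), n_s), 19, n_s),
    target_levels
  )
  dimnames(m) <- list(c(paste0("bg", 1:19), "target"), samples)
  expr <- matrix_to_expr(m)
  spikes <- tidyr::crossing(
    tibble::tibble(ercc_id = c("min", "mid", "hi"),
                   concentration = c(1, 4, 16)),
    sample_id = samples
  ) |>
    dplyr::mutate(
      intensity = 2^(spike_level + log2(concentration)),
      is_min = ercc_id == "min"
    )
  list(expr = expr, spikes = spikes)
}

test_that("detection needs SNR > 5 once and the spike floor beaten in
           more than min_samples samples", {
  # above the minimum spike (level 6) in 5 of 10 samples, high SNR
  fx <- detect_fixture(c(rep(10, 5), rep(0.5, 5)))
  det <- detect_genes(fx$expr, fx$spikes)
  tg <- dplyr::filter(det$per_gene, gene_id == "target")
  expect_true(tg$detected)
  expect_equal(tg$n_samples_above_ercc, 5)
  # above in exactly 3 samples: strict > 3 rejects
  fx3 <- detect_fixture(c(rep(10, 3), rep(0.5, 7)))
  tg3 <- dplyr::filter(detect_genes(fx3$expr, fx3$spikes)$per_gene,
                       gene_id == "target")
  expect_false(tg3$detected)
  expect_equal(tg3$n_samples_above_ercc, 3)
})

test_that("the count comparison alone can satisfy the spike filter", {
  # calibration slope < 0 is impossible here, so build a ladder whose
  # fitted line predicts counts above the minimum spike's count for
  # levels below the spike's own intensity: put the spike's observed
  # intensity above its fitted value
  samples <- paste0("s", 1:10)
  spikes <- tidyr::crossing(
    tibble::tibble(ercc_id = c("min", "mid", "hi"),
                   concentration = c(1, 4, 16)),
    sample_id = samples
  ) |>
    dplyr::mutate(
      # fitted line through (5,0),(7,2),(9,4): log2count = intensity - 5
      # but the min spike's *observed* intensity is inflated to 6.5
      intensity = dplyr::case_when(
        ercc_id == "min" ~ 2^6.5,
        ercc_id == "mid" ~ 2^7,
        TRUE ~ 2^9
      ),
      is_min = ercc_id == "min"
    )
  fit <- fit_ercc_model(spikes)
  # gene at level 6.2: below the observed spike intensity (6.5) in every
  # sample, but predicted count exceeds log2(min concentration) = 0
  stopifnot(predict_log2_count(fit, 6.2) > 0)
  target <- rep(6.2, 10)
  m <- rbind(matrix(rep(seq(0.1, 2, length.out = 19), 10), 19, 10),
             target)
  dimnames(m) <- list(c(paste0("bg", 1:19), "target"), samples)
  det <- detect_genes(matrix_to_expr(m), spikes)
  ps <- dplyr::filter(det$per_sample, gene_id == "target")
  expect_true(all(!ps$above_ercc_intensity))
  expect_true(all(ps$above_ercc_count))
  expect_true(dplyr::filter(det$per_gene,
                            gene_id == "target")$detected)
})

test_that("raising a gene's levels never un-detects it", {
  withr::local_seed(21)
  fx <- detect_fixture(runif(10, 4, 8))
  det1 <- detect_genes(fx$expr, fx$spikes)
  bumped <- fx$expr
  for (s in paste0("s", 1:10)) {
    bumped[[s]][bumped$gene_id == "target"] <-
      bumped[[s]][bumped$gene_id == "target"] + 3
  }
  det2 <- detect_genes(bumped, fx$spikes)
  was <- dplyr::filter(det1$per_gene, gene_id == "target")$detected
  now <- dplyr::filter(det2$per_gene, gene_id == "target")$detected
  expect_true(!was || now)
  expect_true(now >= was)
})

test_that("genes below the noise floor are never detected and rerunning
           is deterministic", {
  st <- small_study(n_genes = 100, seed = 31)
  spikes <- spike_ercc(st$design, noise_sd = 0, seed = 31)
  det <- detect_genes(st$expr, spikes)
  low <- st$truths$gene_id[!st$truths$detectable]
  flagged <- detected_genes(det)
  expect_length(intersect(low, flagged), 0)
  # genes whose level never clears the per-sample noise floor by 5 sigma
  # are never detected, whatever the spike comparison says
  never_above <- det$per_sample |>
    dplyr::group_by(gene_id) |>
    dplyr::summarise(any_above = any(above_snr)) |>
    dplyr::filter(!any_above)
  expect_length(intersect(never_above$gene_id, flagged), 0)
  # detectable genes well above the spike floor always come through
  strong <- st$truths$gene_id[st$truths$detectable &
                                st$truths$baseline > 7]
  expect_true(all(strong %in% flagged))
  det2 <- detect_genes(st$expr, spikes)
  expect_identical(det$per_gene, det2$per_gene)
})
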