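test_that("standardization gives mean 0, unit sd, and rejects constants", {
  expect_equal(standardize_series(c(1, 2, 3)), c(-1, 0, 1))
  expect_error(standardize_series(c(5, 5, 5)), "constant")
  expect_error(standardize_series(c(1, 2)), "short")
  withr::local_seed(8)
  for (rep in 1:5) {
    x <- standardize_series(rnorm(10))
    expect_lt(abs(mean(x)), 1e-12)
    expect_equal(sd(x), 1, tolerance = 1e-12)
  }
})

test_that("Fourier score matches hand values and the complex oracle", {
  t <- seq(0, 21, by = 3)
  x24 <- standardize_series(cos(2 * pi * t / 24))
  expect_equal(fourier_score(x24, t), sqrt(28), tolerance = 1e-10)
  # a 12 h cosine is orthogonal to the 24 h basis on this grid
  x12 <- cos(2 * pi * t / 12)
  x12 <- standardize_series(x12 + 1e-9 * seq_along(t))
  expect_lt(fourier_score(x12, t), 1e-6)
  expect_error(fourier_score(x24, t[-1]), "length")
  withr::local_seed(9)
  for (rep in 1:20) {
    x <- standardize_series(rnorm(length(t)))
    expect_equal(fourier_score(x, t, 24), oracle_fourier(x, t, 24),
                 tolerance = 1e-10)
    expect_equal(fourier_score(x, t, 12), oracle_fourier(x, t, 12),
                 tolerance = 1e-10)
  }
})

test_that("AR1 fitting uses 1/n covariance divisors and recovers phi", {
  expect_equal(fit_ar1(c(1, -1, 1, -1))$phi, -0.75)
  withr::local_seed(10)
  white <- rnorm(5000)
  expect_lt(abs(fit_ar1(white)$phi), 0.05)
  sim <- simulate_background(list(phi = 0.6, innovation_sd = 1), 2000,
                             seed = 11)
  expect_lt(abs(fit_ar1(sim)$phi - 0.6), 0.06)
  # stationary start: variance close to sd^2/(1-phi^2)
  expect_lt(abs(var(sim) - 1 / (1 - 0.36)) / (1 / (1 - 0.36)), 0.15)
  expect_identical(simulate_background(list(phi = 0.2, innovation_sd = 1),
                                       50, seed = 3),
                   simulate_background(list(phi = 0.2, innovation_sd = 1),
                                       50, seed = 3))
})

test_that("the ratio FDR estimator counts correctly, is monotone in F,
           and is scale invariant", {
  # observed {5, 1}; two background sets each scoring {1, 1}
  f_bg <- matrix(1, 2, 2)
  fdr <- fdr_from_scores(c(5, 1), f_bg)
  expect_equal(fdr, c(0, 1))
  withr::local_seed(12)
  f_obs <- rexp(40)
  bg <- matrix(rexp(40 * 20), 40, 20)
  fdr <- fdr_from_scores(f_obs, bg)
  ord <- order(f_obs)
  expect_true(all(diff(fdr[ord]) <= 1e-12))
  expect_true(all(fdr >= 0 & fdr <= 1))
  # multiplying every score by c > 0 changes nothing
  expect_equal(fdr_from_scores(3.7 * f_obs, 3.7 * bg), fdr)
  # tied scores share one FDR
  fdr_t <- fdr_from_scores(c(2, 2, 1), matrix(c(1, 3), 3, 4))
  expect_equal(fdr_t[1], fdr_t[2])
})

test_that("diel calling recovers planted genes and their phases", {
  st <- small_study(n_genes = 150, seed = 5, noise_sd = 0.5,
                    prop_diel = 0.2, amplitude = 1.5)  # 3x noise sd
  scan <- fdr_fourier(st$expr, st$design, B = 200, seed = 6)
  res <- dplyr::inner_join(scan$results, st$truths, by = "gene_id")
  truly <- res$is_diel.y
  called <- res$is_diel.x
  sens <- sum(called & truly) / sum(truly)
  expect_gte(sens, 0.85)
  # phase recovery: peak label within one 3 h grid step of the planted
  # phase for at least 90% of the true diel genes
  pk <- peak_times(st$expr, st$design)
  diel <- dplyr::inner_join(pk,
                            dplyr::filter(st$truths, is_diel),
                            by = "gene_id")
  got_h <- label_phase_hours(collapse_label(diel$peak_label), 12)
  # nearest sampled clock hour to the planted peak, on the sunrise clock
  grid_clock <- unique(st$design$clock_hour)
  grid_sunrise <- (grid_clock - 6) %% 24
  want_h <- vapply(diel$peak_phase, function(ph) {
    g <- grid_sunrise[which.min(circular_shift((ph - 6) %% 24,
                                               grid_sunrise))]
    g
  }, numeric(1))
  hit <- circular_shift(got_h, want_h) <= 3
  expect_gte(mean(hit), 0.9)
})

test_that("noiseless peak and trough labels are exact, with replicate
           and day averaging", {
  design <- make_design(10, 3, 2, 6, 12)
  truths <- tibble::tibble(
    gene_id = "g1", sublineage = "A1", pathway = "p", is_diel = TRUE,
    peak_phase = 18, amplitude = 1, baseline = 5, ar1_phi = 0,
    detectable = TRUE
  )  # 18:00 clock = L12 (sunset)
  e <- simulate_expression(design, truths, noise_sd = 0, seed = 1)
  pk <- peak_times(e, design)
  expect_equal(pk$peak_label, "L12")
  expect_equal(pk$trough_label, "D12")  # antiphase = sunrise

  # replicate means: (3+5)/2 = 4 at L6 loses to 4.5 at L9
  d3 <- make_design(3, 3, 2, 6, 12)  # L3, L6, L9 with duplicates
  m <- matrix(c(0, 0, 3, 5, 4.5, 4.5), 1, 6,
              dimnames = list("g", d3$sample_id))
  expect_equal(peak_time(drop(m), d3), "L9")
  # day averaging: L6 and 2L6 collapse to one L6 value
  d10 <- make_design(10, 3, 1, 6, 12)
  vals <- setNames(rep(0, 10), d10$phase_label)
  vals["L6"] <- 4
  vals["2L6"] <- 6
  m10 <- matrix(vals, 1, 10, dimnames = list("g", d10$sample_id))
  expect_equal(peak_time(drop(m10), d10), "L6")
})

test_that("anti-phased profile groups form two fully supported clusters", {
  design <- make_design(10, 3, 1, 6, 12)
  t <- design$clock_hour
  mk <- function(ph, amp) 5 + amp * cos(2 * pi * (t - ph) / 24)
  m <- rbind(
    t(sapply(c(6, 6.2, 5.8), function(p) mk(p, 1))),
    t(sapply(c(18, 18.2, 17.8), function(p) mk(p, 1)))
  )
  rownames(m) <- paste0("g", 1:6)
  colnames(m) <- design$sample_id
  cl <- cluster_diel_profiles(matrix_to_expr(m), design, n_boot = 100,
                              seed = 2)
  expect_equal(nrow(cl$clusters), 2)
  expect_true(all(cl$clusters$support == 1))
  expect_equal(sort(as.integer(table(cl$assignments$cluster_id))),
               c(3L, 3L))
  grp <- split(cl$assignments$id, cl$assignments$cluster_id)
  expect_true(setequal(grp[[1]], c("g1", "g2", "g3")) ||
                setequal(grp[[1]], c("g4", "g5", "g6")))
  # identical profiles collapse to a single cluster
  same <- matrix(rep(mk(6, 1), 4), 4, 10, byrow = TRUE,
                 dimnames = list(paste0("g", 1:4), design$sample_id))
  cl1 <- cluster_diel_profiles(matrix_to_expr(same), design,
                               n_boot = 50, seed = 2)
  expect_equal(nrow(cl1$clusters), 1)
  expect_equal(cl1$clusters$size, 4)
  # seeded determinism
  cl2 <- cluster_diel_profiles(matrix_to_expr(m), design, n_boot = 100,
                               seed = 2)
  expect_identical(cl$node_support, cl2$node_support)
})
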