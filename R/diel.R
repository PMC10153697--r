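#' Standardize an expression series
#'
#' Centers to mean 0 and scales to unit sample standard deviation.
#'
#' @param x Numeric vector of length >= 3.
#' @return Standardized vector.
#' @export
standardize_series <- function(x) {
  if (length(x) < 3) stop("series too short to standardize", call. = FALSE)
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    stop("constant series cannot be standardized", call. = FALSE)
  }
  (x - mean(x)) / s
}

#' Fourier score of a standardized series
#'
#' The magnitude of the series' projection onto cosine and sine at the
#' target period: `F = sqrt((sum x cos(wt))^2 + (sum x sin(wt))^2)` with
#' `w = 2*pi/period`. Large scores indicate strong periodicity at that
#' period.
#'
#' @param x Standardized series (see [standardize_series()]).
#' @param t Sampling times in hours (regular grid; replicates
#'   pre-averaged).
#' @param period Target period in hours.
#' @return Non-negative Fourier score.
#' @export
fourier_score <- function(x, t, period = 24) {
  if (length(x) != length(t)) {
    stop("`x` and `t` must have the same length", call. = FALSE)
  }
  w <- 2 * pi / period
  sqrt(sum(x * cos(w * t))^2 + sum(x * sin(w * t))^2)
}

#' Fit a first-order autoregressive model
#'
#' The lag-1 autocorrelation is estimated with 1/n covariance divisors on
#' the demeaned series (the standard moment estimator); the innovation
#' standard deviation follows from the stationarity relation
#' `var = innovation_sd^2 / (1 - phi^2)`.
#'
#' @param x Numeric series of length >= 4.
#' @return List of class `ar1_model` with `phi` and `innovation_sd`.
#' @export
fit_ar1 <- function(x) {
  n <- length(x)
  if (n < 4) stop("series too short for an AR1 fit", call. = FALSE)
  xc <- x - mean(x)
  g0 <- sum(xc^2) / n
  if (g0 == 0) stop("constant series cannot be fit", call. = FALSE)
  g1 <- sum(xc[-n] * xc[-1]) / n
  phi <- g1 / g0
  phi <- max(min(phi, 0.99), -0.99)
  structure(list(phi = phi,
                 innovation_sd = sqrt(max(g0 * (1 - phi^2), 0))),
            class = "ar1_model")
}

#' Simulate an AR1 background series
#'
#' Starts at the stationary distribution (no burn-in) so the series is a
#' draw from the fitted process.
#'
#' @param model An `ar1_model` (or list with `phi`, `innovation_sd`).
#' @param n Length of the series.
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n`.
#' @export
simulate_background <- function(model, n, seed = NULL) {
  run <- function() drop(ar1_noise(1, n, model$phi, model$innovation_sd))
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# average replicates onto the regular time grid:
# genes x timepoints matrix plus the grid itself
average_replicates <- function(expr, design) {
  m <- expr_to_matrix(expr)
  m <- m[, design$sample_id, drop = FALSE]
  grid <- sort(unique(design$hours_since_start))
  tp <- factor(design$hours_since_start, levels = grid)
  avg <- t(apply(m, 1, function(row) tapply(row, tp, mean)))
  colnames(avg) <- as.character(grid)
  list(m = avg, t = grid)
}

#' Ratio-based FDR from observed and background scores
#'
#' For each observed score `F`, the raw estimate is
#' `min(1, mean_b #\{background in set b >= F\} / #\{observed >= F\})`;
#' the result is then made non-increasing in `F` by giving each score the
#' minimum raw estimate among thresholds at or below it. Tied scores share
#' one FDR. The estimate is invariant to multiplying all scores (observed
#' and background) by any positive constant.
#'
#' @param f_obs Numeric vector of observed scores.
#' @param f_bg Numeric matrix of background scores, one column per
#'   background set (rows need not align with `f_obs`).
#' @return Numeric FDR vector aligned with `f_obs`.
#' @export
fdr_from_scores <- function(f_obs, f_bg) {
  f_bg <- as.matrix(f_bg)
  B <- ncol(f_bg)
  sf <- sort(as.vector(f_bg))
  bg_ge <- length(sf) - findInterval(f_obs - 1e-12, sf)
  obs_ge <- vapply(f_obs, function(f) sum(f_obs >= f), numeric(1))
  raw <- pmin(1, (bg_ge / B) / obs_ge)
  ord <- order(f_obs)
  fdr <- numeric(length(f_obs))
  fdr[ord] <- cummin(raw[ord])
  fdr
}

#' Call diel genes by Fourier score against AR1 backgrounds
#'
#' Per gene, replicates are averaged onto the regular time grid, the series
#' is standardized and its Fourier score at the target period computed.
#' Significance comes from `B` background data sets: each contains one AR1
#' surrogate per gene, simulated from that gene's own fitted lag-1
#' autocorrelation, standardized and scored the same way. The false
#' discovery rate at a gene's score `F` is the plug-in ratio
#' `min(1, mean_b #\{background >= F\} / #\{observed >= F\})`, made
#' non-increasing in `F` by taking, for each gene, the minimum raw estimate
#' over thresholds at or below its score. Genes tied on `F` share one FDR.
#' A gene is diel when its FDR is below `fdr_threshold`.
#'
#' @param expr Wide gene expression tibble (log2), usually restricted to
#'   detected genes.
#' @param design Design tibble matching the expression columns.
#' @param B Number of background data sets.
#' @param period Target period in hours.
#' @param fdr_threshold Diel call threshold on the FDR.
#' @param seed Integer seed for the background simulations.
#' @return An object of class `diel_scan`: `results` tibble (`gene_id`,
#'   `fourier_score`, `ar1_phi`, `fdr`, `is_diel`) plus the scan
#'   parameters.
#' @export
fdr_fourier <- function(expr, design, B = 1000, period = 24,
                        fdr_threshold = 0.25, seed = 1L) {
  if (nrow(expr) < 2) stop("need >= 2 genes to estimate an FDR",
                           call. = FALSE)
  if (B < 10) warning("B < 10 background sets gives an unstable FDR")
  avg <- average_replicates(expr, design)
  m <- avg$m
  t_grid <- avg$t
  n_tp <- length(t_grid)
  constant <- apply(m, 1, sd) == 0
  if (any(constant)) {
    warning(sum(constant), " constant gene(s) excluded from scoring")
  }
  live <- which(!constant)
  x_std <- t(apply(m[live, , drop = FALSE], 1, standardize_series))
  w <- 2 * pi / period
  basis <- cbind(cos(w * t_grid), sin(w * t_grid))
  f_obs <- sqrt(rowSums((x_std %*% basis)^2))
  phi <- vapply(live, function(i) fit_ar1(m[i, ])$phi, numeric(1))
  n_live <- length(live)
  f_bg <- withr::with_seed(seed, {
    vapply(seq_len(B), function(b) {
      sur <- ar1_noise(n_live, n_tp, phi, 1)
      sur <- sur - rowMeans(sur)
      sur <- sur / sqrt(rowSums(sur^2) / (n_tp - 1))
      sqrt(rowSums((sur %*% basis)^2))
    }, numeric(n_live))
  })
  f_bg <- matrix(f_bg, nrow = n_live)
  fdr <- fdr_from_scores(f_obs, f_bg)
  results <- tibble::tibble(
    gene_id = rownames(m),
    fourier_score = NA_real_, ar1_phi = NA_real_, fdr = NA_real_,
    is_diel = FALSE
  )
  results$fourier_score[live] <- f_obs
  results$ar1_phi[live] <- phi
  results$fdr[live] <- fdr
  results$is_diel[live] <- fdr < fdr_threshold
  structure(list(results = results, B = B, period = period,
                 fdr_threshold = fdr_threshold, seed = seed,
                 t_grid = t_grid),
            class = "diel_scan")
}

#' @export
print.diel_scan <- function(x, ...) {
  cat("<diel_scan> ", sum(x$results$is_diel, na.rm = TRUE), " of ",
      nrow(x$results), " genes diel (period ", x$period, " h, FDR < ",
      x$fdr_threshold, ", B = ", x$B, ")\n", sep = "")
  invisible(x)
}

# replicate-mean then day-mean per collapsed phase label;
# returns genes x labels matrix with labels in timeline order
day_mean_profiles <- function(expr, design) {
  m <- expr_to_matrix(expr)
  m <- m[, design$sample_id, drop = FALSE]
  lab <- collapse_label(design$phase_label)
  # replicate means within each original time point first
  tp <- design$phase_label
  rep_mean <- t(apply(m, 1, function(row) tapply(row, tp, mean)))
  tp_first <- tapply(design$hours_since_start, tp, min)
  tp_lab <- collapse_label(colnames(rep_mean))
  day_mean <- t(apply(rep_mean, 1, function(row) tapply(row, tp_lab, mean)))
  lab_first <- tapply(tp_first[colnames(rep_mean)], tp_lab, min)
  ordered <- names(sort(lab_first))
  day_mean <- day_mean[, ordered, drop = FALSE]
  if (nrow(day_mean) != nrow(m)) day_mean <- t(day_mean)  # single label
  rownames(day_mean) <- rownames(m)
  day_mean
}

#' Peak and trough times of day
#'
#' Transcript levels are averaged over replicates and then over days (so
#' `L6` and `2L6` contribute to one `L6` value); the peak is the collapsed
#' phase label with the highest average level and the trough the lowest.
#' Ties break to the earliest label in timeline order.
#'
#' @param expr Wide gene expression tibble.
#' @param design Matching design tibble.
#' @return Tibble with `gene_id`, `peak_label`, `trough_label`.
#' @export
peak_times <- function(expr, design) {
  prof <- day_mean_profiles(expr, design)
  labs <- colnames(prof)
  tibble::tibble(
    gene_id = rownames(prof),
    peak_label = labs[apply(prof, 1, which.max)],
    trough_label = labs[apply(prof, 1, which.min)]
  )
}

#' @param gene_row Numeric vector of one gene's levels (design order).
#' @rdname peak_times
#' @export
peak_time <- function(gene_row, design) {
  expr <- matrix_to_expr(matrix(gene_row, nrow = 1,
                                dimnames = list("g", design$sample_id)))
  peak_times(expr, design)$peak_label
}

#' @rdname peak_times
#' @export
trough_time <- function(gene_row, design) {
  expr <- matrix_to_expr(matrix(gene_row, nrow = 1,
                                dimnames = list("g", design$sample_id)))
  peak_times(expr, design)$trough_label
}
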