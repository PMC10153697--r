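#' Per-sample noise floor
#'
#' The noise floor of a sample is estimated from the bottom decile of gene
#' transcript levels: `mu_noise` is their median and `sigma_noise` their
#' sample standard deviation. At least two genes are always used.
#'
#' @param levels Numeric vector of one sample's gene-level log2 values.
#' @param decile Fraction of genes defining the floor (default 0.10).
#' @return Named numeric vector `c(mu_noise, sigma_noise)`.
#' @export
noise_floor <- function(levels, decile = 0.10) {
  g <- length(levels)
  if (g < 20) stop("need >= 20 genes to estimate a noise floor",
                   call. = FALSE)
  n_low <- max(2L, floor(decile * g))
  low <- sort(levels)[seq_len(n_low)]
  sigma <- sd(low)
  if (sigma == 0) {
    stop(paste("zero spread in the bottom decile; the noise floor is",
               "degenerate (see `sigma_fallback` in detect_genes)"),
         call. = FALSE)
  }
  c(mu_noise = median(low), sigma_noise = sigma)
}

#' Signal-to-noise ratio
#'
#' `snr()` is the z-score of a transcript level against the sample's noise
#' floor. `detect_snr()` applies it column-wise and flags genes with
#' SNR strictly greater than the threshold.
#'
#' @param level Transcript level(s), log2.
#' @param mu_noise,sigma_noise Noise floor from [noise_floor()].
#' @return `snr()`: numeric SNR values.
#' @export
snr <- function(level, mu_noise, sigma_noise) {
  stopifnot(sigma_noise > 0)
  (level - mu_noise) / sigma_noise
}

#' @param expr Wide gene expression tibble (log2).
#' @param threshold SNR detection threshold (strict `>`).
#' @param decile Passed to [noise_floor()].
#' @return `detect_snr()`: long tibble `gene_id`, `sample_id`, `snr`,
#'   `above_snr`.
#' @rdname snr
#' @export
detect_snr <- function(expr, threshold = 5, decile = 0.10) {
  m <- expr_to_matrix(expr)
  purrr::map_dfr(colnames(m), function(s) {
    fl <- noise_floor(m[, s], decile = decile)
    z <- snr(m[, s], fl[["mu_noise"]], fl[["sigma_noise"]])
    tibble::tibble(gene_id = rownames(m), sample_id = s,
                   snr = unname(z), above_snr = unname(z > threshold))
  })
}

#' Fit the spike-in calibration model
#'
#' Ordinary least squares of log2 transcript count (proportional to spike
#' concentration) on log2 array intensity, fitted on the per-sample mean
#' intensity of each spike. The model converts array intensities into
#' predicted transcript counts.
#'
#' @param spikes Long spike tibble from [spike_ercc()] (columns `ercc_id`,
#'   `concentration`, `intensity`).
#' @return An object of class `ercc_model`: the underlying `lm` plus
#'   `slope`, `intercept`, `r_squared`, `n_levels`.
#' @export
fit_ercc_model <- function(spikes) {
  lev <- spikes |>
    dplyr::group_by(.data$ercc_id, .data$concentration) |>
    dplyr::summarise(log2_intensity = mean(log2(.data$intensity)),
                     .groups = "drop")
  if (dplyr::n_distinct(lev$concentration) < 3) {
    stop("need >= 3 distinct spike concentrations", call. = FALSE)
  }
  if (sd(lev$log2_intensity) == 0) {
    stop("spike intensities are constant; calibration fit is singular",
         call. = FALSE)
  }
  lev$log2_count <- log2(lev$concentration)
  fit <- lm(log2_count ~ log2_intensity, data = lev)
  structure(
    list(fit = fit,
         slope = unname(coef(fit)[2]),
         intercept = unname(coef(fit)[1]),
         r_squared = suppressWarnings(summary(fit)$r.squared),
         n_levels = dplyr::n_distinct(lev$concentration)),
    class = "ercc_model"
  )
}

#' @export
print.ercc_model <- function(x, ...) {
  cat("<ercc_model> log2(count) = ", format(x$intercept), " + ",
      format(x$slope), " * log2(intensity); R^2 = ",
      format(x$r_squared, digits = 4), ", ", x$n_levels, " levels\n",
      sep = "")
  invisible(x)
}

#' Predict log2 transcript count from log2 intensity
#'
#' @param model An `ercc_model`.
#' @param log2_intensity Log2 array intensities.
#' @return Predicted log2 counts.
#' @export
predict_log2_count <- function(model, log2_intensity) {
  model$intercept + model$slope * log2_intensity
}

#' Spike-in-calibrated gene detection
#'
#' A gene is detected when (a) its SNR exceeds `snr_threshold` in at least
#' `min_snr_samples` samples, and (b) in strictly more than `min_samples`
#' samples its transcript level exceeds the least concentrated spike by
#' either of two comparisons: (i) log2 array intensity of the gene versus
#' the spike's per-sample intensity, or (ii) the gene's predicted log2
#' transcript count (from the spike calibration model) versus the spike's
#' log2 count.
#'
#' @param expr Wide gene expression tibble (log2).
#' @param spikes Long spike tibble from [spike_ercc()]; its
#'   minimum-concentration member bounds detection.
#' @param snr_threshold SNR threshold (strict `>`).
#' @param min_samples Gene must beat the spike in strictly more than this
#'   many samples.
#' @param min_snr_samples Minimum samples with SNR above threshold.
#' @param decile Noise-floor decile.
#' @return A list of class `detection_table`: `per_sample` (long tibble
#'   with `snr`, `above_snr`, `above_ercc_intensity`, `above_ercc_count`),
#'   `per_gene` (tibble with `n_samples_snr`, `n_samples_above_ercc`,
#'   `detected`), and the fitted `ercc_model`.
#' @export
detect_genes <- function(expr, spikes, snr_threshold = 5, min_samples = 3,
                         min_snr_samples = 1, decile = 0.10) {
  model <- fit_ercc_model(spikes)
  m <- expr_to_matrix(expr)
  snr_tbl <- detect_snr(expr, threshold = snr_threshold, decile = decile)
  min_spike <- spikes |>
    dplyr::filter(.data$concentration == min(.data$concentration))
  if (nrow(min_spike) == 0) stop("no minimum-concentration spike",
                                 call. = FALSE)
  floor_by_sample <- min_spike |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(floor_log2 = mean(log2(.data$intensity)),
                     .groups = "drop")
  floor_count <- log2(min(min_spike$concentration))
  per_sample <- snr_tbl |>
    dplyr::left_join(
      tidyr::pivot_longer(expr, -"gene_id", names_to = "sample_id",
                          values_to = "level"),
      by = c("gene_id", "sample_id")
    ) |>
    dplyr::left_join(floor_by_sample, by = "sample_id") |>
    dplyr::mutate(
      above_ercc_intensity = .data$level > .data$floor_log2,
      above_ercc_count =
        predict_log2_count(model, .data$level) > floor_count
    )
  per_gene <- per_sample |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      n_samples_snr = sum(.data$above_snr),
      n_samples_above_ercc = sum(.data$above_ercc_intensity |
                                   .data$above_ercc_count),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      detected = .data$n_samples_snr >= min_snr_samples &
        .data$n_samples_above_ercc > min_samples
    )
  structure(list(per_sample = per_sample, per_gene = per_gene,
                 ercc_model = model,
                 snr_threshold = snr_threshold, min_samples = min_samples),
            class = "detection_table")
}

#' @export
print.detection_table <- function(x, ...) {
  cat("<detection_table> ", sum(x$per_gene$detected), " of ",
      nrow(x$per_gene), " genes detected (SNR > ", x$snr_threshold,
      ", above spike floor in > ", x$min_samples, " samples)\n", sep = "")
  invisible(x)
}

#' Detected gene ids
#'
#' @param det A `detection_table`.
#' @return Character vector of detected gene ids.
#' @export
detected_genes <- function(det) {
  det$per_gene$gene_id[det$per_gene$detected]
}
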