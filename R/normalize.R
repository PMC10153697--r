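#' Quantile-normalize probe intensities across samples
#'
#' Forces every sample (column) to share the same empirical distribution:
#' the reference distribution is the across-sample mean of order statistics,
#' and each value is replaced by the reference value at its within-column
#' rank. Ties within a column receive the mean of the reference values they
#' span, which makes the operation independent of input row order and
#' idempotent.
#'
#' @param probes Wide tibble: `probe_id` (or `gene_id`) plus one numeric
#'   column per sample, linear or log scale.
#' @return A tibble of the same shape with normalized values.
#' @export
quantile_normalize <- function(probes) {
  m <- expr_to_matrix(probes)
  if (any(!is.finite(m))) stop("missing or non-finite intensities",
                               call. = FALSE)
  if (ncol(m) < 2) {
    warning("single sample: quantile normalization is the identity")
    return(probes)
  }
  ref <- rowMeans(apply(m, 2, sort))
  cs <- cumsum(c(0, ref))
  out <- apply(m, 2, function(col) {
    # ties share the mean of all reference values across their rank range
    r_min <- rank(col, ties.method = "min")
    r_max <- rank(col, ties.method = "max")
    (cs[r_max + 1] - cs[r_min]) / (r_max - r_min + 1)
  })
  dimnames(out) <- dimnames(m)
  id_col <- names(probes)[1]
  matrix_to_expr(out, id_col = id_col)
}

# Tukey median polish on a log2 probe x sample block; gene level per sample
# is overall + column effect. Row sweeps first (stats::medpolish default).
polish_block <- function(block_log2, max_iter = 10, tol = 0.01) {
  if (nrow(block_log2) == 1) return(drop(block_log2))
  fit <- stats::medpolish(block_log2, eps = tol, maxiter = max_iter,
                          trace.iter = FALSE)
  fit$overall + fit$col
}

#' Summarize probe sets to gene-level transcript levels
#'
#' Log2-transforms the (already quantile-normalized) probe intensities and,
#' per gene, decomposes the probe x sample block by Tukey median polish
#' into overall + probe effect + sample effect + residual. The gene's
#' transcript level in each sample is overall + sample effect, which is
#' robust to probes with systematically different affinities.
#'
#' @param probes Wide probe tibble (linear scale), quantile-normalized.
#' @param platform A `platform_design` or annotation tibble mapping
#'   `probe_id` to `gene_id`.
#' @param max_iter Maximum median-polish sweeps.
#' @param tol Convergence tolerance on the residual change.
#' @return A wide gene tibble (`gene_id` + sample columns, log2 scale) with
#'   a `probe_count` attribute (named integer vector).
#' @export
median_polish_summarize <- function(probes, platform, max_iter = 10,
                                    tol = 0.01) {
  ann <- if (inherits(platform, "platform_design")) platform$probes
         else platform
  m <- log2(expr_to_matrix(probes))
  map <- ann$gene_id[match(rownames(m), ann$probe_id)]
  orphan <- rownames(m)[is.na(map)]
  if (length(orphan) > 0) {
    warning("dropping ", length(orphan), " probe(s) absent from platform")
    m <- m[!is.na(map), , drop = FALSE]
    map <- map[!is.na(map)]
  }
  genes <- unique(ann$gene_id)
  genes <- genes[genes %in% map]
  if (length(genes) < length(unique(ann$gene_id))) {
    warning("omitting ", length(unique(ann$gene_id)) - length(genes),
            " gene(s) with zero probes")
  }
  rows <- split(seq_len(nrow(m)), factor(map, levels = genes))
  out <- t(vapply(rows, function(idx) {
    polish_block(m[idx, , drop = FALSE], max_iter = max_iter, tol = tol)
  }, numeric(ncol(m))))
  colnames(out) <- colnames(m)
  res <- matrix_to_expr(out, id_col = "gene_id")
  attr(res, "probe_count") <- vapply(rows, length, integer(1))
  res
}
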