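#' Plot diel expression profiles
#'
#' Standardized transcript levels over the time course for a set of genes,
#' one line per gene, optionally faceted by a grouping (e.g. diel cluster).
#'
#' @param expr Wide gene expression tibble.
#' @param design Matching design tibble.
#' @param genes Gene ids to show (default: all rows of `expr`).
#' @param groups Optional tibble with `gene_id` and a `group` column used
#'   for facets.
#' @return A ggplot object.
#' @export
plot_diel_profiles <- function(expr, design, genes = NULL, groups = NULL) {
  if (!is.null(genes)) {
    expr <- dplyr::filter(expr, .data$gene_id %in% genes)
  }
  avg <- average_replicates(expr, design)
  std <- t(apply(avg$m, 1, standardize_series))
  rownames(std) <- rownames(avg$m)
  long <- matrix_to_expr(std) |>
    tidyr::pivot_longer(-"gene_id", names_to = "hours",
                        values_to = "level") |>
    dplyr::mutate(hours = as.numeric(.data$hours))
  if (!is.null(groups)) {
    long <- dplyr::left_join(long, groups, by = "gene_id")
  }
  p <- ggplot2::ggplot(long,
                       ggplot2::aes(x = .data$hours, y = .data$level,
                                    group = .data$gene_id)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "hours since first sample",
                  y = "standardized transcript level") +
    ggplot2::theme_minimal()
  if (!is.null(groups)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$group))
  }
  p
}

#' Histogram of peak times
#'
#' Percentage of genes peaking at each time-of-day label, optionally by
#' sublineage.
#'
#' @param peaks Tibble from [peak_times()].
#' @param design Design tibble (fixes the label order).
#' @param annotation Optional tibble with `gene_id`, `sublineage`.
#' @return A ggplot object.
#' @export
plot_peak_histogram <- function(peaks, design, annotation = NULL) {
  labs <- unique(collapse_label(
    design$phase_label[order(design$hours_since_start)]))
  d <- dplyr::mutate(peaks,
                     peak_label = factor(.data$peak_label, levels = labs))
  if (!is.null(annotation)) {
    d <- dplyr::left_join(d, annotation, by = "gene_id")
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$peak_label)) +
    ggplot2::geom_bar(ggplot2::aes(y = ggplot2::after_stat(prop),
                                   group = 1)) +
    ggplot2::scale_y_continuous(labels = function(x) 100 * x) +
    ggplot2::labs(x = "time of peak transcript level",
                  y = "% of detected genes") +
    ggplot2::theme_minimal()
  if (!is.null(annotation) && "sublineage" %in% names(d)) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$sublineage))
  }
  p
}

#' Pathway quantile heat map
#'
#' @param pm Result of [pathway_matrix()].
#' @return A ggplot object.
#' @export
plot_pathway_matrix <- function(pm) {
  long <- tidyr::pivot_longer(pm$matrix, -"pathway",
                              names_to = "source",
                              values_to = "quantile")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$source, y = .data$pathway,
                                     fill = .data$quantile)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "quantile") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.diel_scan <- function(object, ...) {
  d <- dplyr::filter(object$results, !is.na(.data$fourier_score))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fourier_score,
                                  y = .data$fdr,
                                  colour = .data$is_diel)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$fdr_threshold,
                        linetype = "dashed") +
    ggplot2::labs(x = "Fourier score", y = "FDR", colour = "diel") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ordination <- function(object, env_vectors = NULL, ...) {
  p <- ggplot2::ggplot(object$coords,
                       ggplot2::aes(x = .data$axis1, y = .data$axis2)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "NMDS1", y = "NMDS2",
      subtitle = paste0("stress = ", format(object$stress, digits = 3))
    ) +
    ggplot2::theme_minimal()
  if (!is.null(env_vectors)) {
    sc <- max(abs(unlist(object$coords[c("axis1", "axis2")])))
    arr <- dplyr::mutate(env_vectors,
                         x = .data$axis1 * sqrt(.data$r_squared) * sc,
                         y = .data$axis2 * sqrt(.data$r_squared) * sc)
    p <- p +
      ggplot2::geom_segment(
        data = arr,
        ggplot2::aes(x = 0, y = 0, xend = .data$x, yend = .data$y,
                     colour = .data$significant),
        arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))) +
      ggplot2::geom_text(
        data = arr,
        ggplot2::aes(x = .data$x, y = .data$y,
                     label = .data$variable),
        vjust = -0.5, size = 3)
  }
  p
}

#' @export
autoplot.ercc_model <- function(object, ...) {
  d <- object$fit$model
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2_intensity,
                                  y = .data$log2_count)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope,
                         intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(x = "log2 spike intensity",
                  y = "log2 transcript count") +
    ggplot2::theme_minimal()
}
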