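#' Tidy and glance methods
#'
#' broom-style accessors for the package's fitted objects: one row per
#' term/gene from `tidy()`, a one-row model summary from `glance()`.
#'
#' @param x A fitted object (`ercc_model`, `diel_scan`,
#'   `detection_table`, `ordination`, `boot_clust`).
#' @param ... Unused.
#' @return A tibble.
#' @name dielarray-tidiers
NULL

#' @rdname dielarray-tidiers
#' @export
tidy.ercc_model <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @rdname dielarray-tidiers
#' @export
glance.ercc_model <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, n_levels = x$n_levels)
}

#' @rdname dielarray-tidiers
#' @export
tidy.diel_scan <- function(x, ...) x$results

#' @rdname dielarray-tidiers
#' @export
glance.diel_scan <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$results),
    n_diel = sum(x$results$is_diel, na.rm = TRUE),
    B = x$B, period = x$period, fdr_threshold = x$fdr_threshold
  )
}

#' @rdname dielarray-tidiers
#' @export
tidy.detection_table <- function(x, ...) x$per_gene

#' @rdname dielarray-tidiers
#' @export
glance.detection_table <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$per_gene),
    n_detected = sum(x$per_gene$detected),
    snr_threshold = x$snr_threshold,
    min_samples = x$min_samples
  )
}

#' @rdname dielarray-tidiers
#' @export
tidy.ordination <- function(x, ...) x$coords

#' @rdname dielarray-tidiers
#' @export
glance.ordination <- function(x, ...) {
  tibble::tibble(n_points = nrow(x$coords), stress = x$stress)
}

#' @rdname dielarray-tidiers
#' @export
tidy.boot_clust <- function(x, ...) x$assignments

#' @rdname dielarray-tidiers
#' @export
glance.boot_clust <- function(x, ...) {
  tibble::tibble(n_clusters = nrow(x$clusters),
                 n_items = nrow(x$assignments))
}
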