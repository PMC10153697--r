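#' Standardized transcript levels at one site
#'
#' Within each sample, transcript levels are converted to z-scores across
#' genes (sample mean 0, sample sd 1, computed over the site's detected
#' genes); a gene's standardized level at the site is the median of its
#' z-scores over all samples. This puts independently normalized sites on
#' one comparable scale.
#'
#' @param expr Wide gene expression tibble (log2) restricted to the site's
#'   detected genes.
#' @param site Optional site label carried into the output.
#' @return Tibble with `gene_id`, `site`, `value`.
#' @export
standardized_level <- function(expr, site = NA_character_) {
  m <- expr_to_matrix(expr)
  if (nrow(m) < 2) stop("need >= 2 genes per sample", call. = FALSE)
  z <- scale(m)  # column-wise: (level - sample mean) / sample sd
  tibble::tibble(
    gene_id = rownames(m),
    site = site,
    value = unname(apply(z, 1, median))
  )
}

#' Detection overlap between two sites
#'
#' @param detected_a,detected_b Character vectors of detected gene ids (or
#'   `detection_table` objects).
#' @return List with `both`, `only_a`, `only_b` (gene id vectors) and
#'   `counts`.
#' @export
detection_overlap <- function(detected_a, detected_b) {
  ga <- if (inherits(detected_a, "detection_table"))
    detected_genes(detected_a) else detected_a
  gb <- if (inherits(detected_b, "detection_table"))
    detected_genes(detected_b) else detected_b
  both <- intersect(ga, gb)
  out <- list(both = both, only_a = setdiff(ga, gb),
              only_b = setdiff(gb, ga))
  out$counts <- vapply(out, length, integer(1))
  out
}

#' Welch two-sample t test
#'
#' Unequal-variance t test with Satterthwaite degrees of freedom (wraps
#' `stats::t.test`).
#'
#' @param group1,group2 Numeric vectors (each length >= 2).
#' @param alternative `"two.sided"`, `"greater"`, or `"less"`.
#' @return Tibble with `t`, `df`, `p`.
#' @export
welch_test <- function(group1, group2, alternative = "two.sided") {
  stopifnot(length(group1) >= 2, length(group2) >= 2)
  ht <- stats::t.test(group1, group2, var.equal = FALSE,
                      alternative = alternative)
  tibble::tibble(t = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p = ht$p.value)
}

#' One-tailed paired or unpaired t tests
#'
#' Paired: a one-sample t test on the gene-aligned differences. Unpaired:
#' a Welch test. The alternative is one-sided by default ("greater": the
#' first group's mean exceeds the second's).
#'
#' @param counts_a,counts_b Numeric vectors; equal length and gene-aligned
#'   when `paired = TRUE`.
#' @param paired Whether the observations are paired by gene.
#' @param alternative One-sided alternative (default `"greater"`).
#' @return Tibble with `t`, `df`, `p`, `n`.
#' @export
paired_unpaired_ttests <- function(counts_a, counts_b, paired = FALSE,
                                   alternative = "greater") {
  if (paired && length(counts_a) != length(counts_b)) {
    stop("paired test needs equal, gene-aligned lengths", call. = FALSE)
  }
  if (paired && sd(counts_a - counts_b) == 0) {
    stop("all paired differences identical: t statistic undefined",
         call. = FALSE)
  }
  ht <- stats::t.test(counts_a, counts_b, paired = paired,
                      var.equal = FALSE, alternative = alternative)
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value,
                 n = if (paired) length(counts_a)
                     else length(counts_a) + length(counts_b))
}

#' Fisher's exact test for diel status by habitat
#'
#' Two-sided exact test on a 2x2 contingency table (wraps
#' `stats::fisher.test`, whose two-sided p sums the probabilities of all
#' tables, at fixed margins, no more likely than the observed one).
#'
#' @param table 2x2 matrix of non-negative integer counts, e.g. rows =
#'   habitat, columns = non-diel/diel.
#' @return Tibble with `odds_ratio` and `p`.
#' @export
fisher_habitat_test <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == c(2, 2)),
            all(table >= 0), all(table == round(table)))
  ht <- stats::fisher.test(table, alternative = "two.sided")
  tibble::tibble(odds_ratio = unname(ht$estimate), p = ht$p.value)
}

#' Correlation between two series
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param method `"pearson"` or `"spearman"`.
#' @return Tibble with `rho` and `p`.
#' @export
correlations <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 3)
  ht <- suppressWarnings(stats::cor.test(x, y, method = method))
  tibble::tibble(rho = unname(ht$estimate), p = ht$p.value)
}

#' Cross-site pathway correlations
#'
#' Per pathway, the Pearson correlation across sites of the genes' median
#' transcript levels, computed for pathways with at least `min_genes`
#' genes detected at both sites.
#'
#' @param levels_a,levels_b Tibbles from [standardized_level()] (or any
#'   tibble with `gene_id` and `value`) for the two sites, restricted to
#'   cross-site detected genes.
#' @param annotation Tibble mapping `gene_id` to `pathway`.
#' @param min_genes Minimum genes per pathway (default 5).
#' @return Tibble with `pathway`, `n_genes`, `rho`, `p`, `significant`.
#' @export
pathway_correlations <- function(levels_a, levels_b, annotation,
                                 min_genes = 5) {
  joined <- dplyr::inner_join(
    dplyr::select(levels_a, "gene_id", a = "value"),
    dplyr::select(levels_b, "gene_id", b = "value"),
    by = "gene_id"
  ) |>
    dplyr::inner_join(dplyr::select(annotation, "gene_id", "pathway"),
                      by = "gene_id")
  keep <- joined |>
    dplyr::count(.data$pathway) |>
    dplyr::filter(.data$n >= min_genes)
  joined <- dplyr::filter(joined, .data$pathway %in% keep$pathway)
  if (nrow(joined) == 0) {
    return(tibble::tibble(pathway = character(0), n_genes = integer(0),
                          rho = numeric(0), p = numeric(0),
                          significant = logical(0)))
  }
  joined |>
    dplyr::group_by(.data$pathway) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      res = correlations(.data$a, .data$b, "pearson"),
      .groups = "drop"
    ) |>
    tidyr::unpack("res") |>
    dplyr::mutate(significant = .data$p < 0.05)
}

# empirical quantile rank on the 5% grid: (rank-1)/(n-1) with mean ranks
# for ties, rounded half-up to the nearest 0.05
quantile_grid <- function(x, grid = 0.05) {
  if (length(x) == 1) return(0.5)
  q <- (rank(x, ties.method = "average") - 1) / (length(x) - 1)
  floor(q / grid + 0.5) * grid
}

#' Pathway quantile matrix
#'
#' Builds the pathway x source grid used to compare expression across
#' sites, sublineages and platforms. For each source (a site/sublineage
#' data set, microarray intensities or sequencing counts), the pathway
#' level in each sample is the median transcript level of the detected
#' genes in the pathway; pathway levels are summarized over samples
#' (median) and converted to empirical quantiles on a 5% grid, which makes
#' columns invariant to any monotone transform and therefore comparable
#' across platforms. Pathways detected in at most one third of a source's
#' samples are dropped from that source.
#'
#' @param sources Named list; each element is a long tibble with columns
#'   `gene_id`, `sample_id`, `level`, and logical `detected`.
#' @param annotation Tibble mapping `gene_id` to `pathway`.
#' @param min_sample_frac A pathway is kept when detected in strictly more
#'   than this fraction of samples (default 1/3).
#' @param cluster_columns If `TRUE` (and >= 2 columns), order columns by
#'   average-linkage clustering of `1 - correlation` distances with
#'   bootstrap support.
#' @param n_boot,alpha,seed Bootstrap parameters for column clustering.
#' @return List with `matrix` (wide tibble: `pathway` + one column per
#'   source, cells on the 5% quantile grid, `NA` where dropped) and
#'   `column_clusters` (a `boot_clust` or `NULL`).
#' @export
pathway_matrix <- function(sources, annotation, min_sample_frac = 1 / 3,
                           cluster_columns = FALSE, n_boot = 100,
                           alpha = 0.95, seed = 1L) {
  stopifnot(is.list(sources), !is.null(names(sources)))
  cols <- purrr::imap(sources, function(tbl, nm) {
    tbl <- dplyr::inner_join(tbl,
                             dplyr::select(annotation, "gene_id",
                                           "pathway"),
                             by = "gene_id")
    n_samples <- dplyr::n_distinct(tbl$sample_id)
    per_sample <- tbl |>
      dplyr::filter(.data$detected) |>
      dplyr::group_by(.data$pathway, .data$sample_id) |>
      dplyr::summarise(level = median(.data$level), .groups = "drop")
    kept <- per_sample |>
      dplyr::count(.data$pathway) |>
      dplyr::filter(.data$n > min_sample_frac * n_samples)
    med <- per_sample |>
      dplyr::filter(.data$pathway %in% kept$pathway) |>
      dplyr::group_by(.data$pathway) |>
      dplyr::summarise(level = median(.data$level), .groups = "drop")
    med$quantile <- quantile_grid(med$level)
    dplyr::select(med, "pathway", !!nm := "quantile")
  })
  wide <- purrr::reduce(cols, dplyr::full_join, by = "pathway") |>
    dplyr::arrange(.data$pathway)
  column_clusters <- NULL
  if (cluster_columns && length(sources) >= 2) {
    m <- t(as.matrix(wide[-1]))
    colnames(m) <- wide$pathway
    m[is.na(m)] <- 0.5  # dropped pathways carry no signal
    column_clusters <- cluster_profiles_boot(
      m, n_boot = n_boot, alpha = alpha, linkage = "average", seed = seed)
  }
  list(matrix = wide, column_clusters = column_clusters)
}

#' Circular peak-time shifts between sites
#'
#' Converts each gene's peak phase labels at two sites to hours since
#' sunrise on a 24 h clock and reports the minimal circular distance
#' between them, categorized as `maintained` (0 h), `shifted_lt6` (< 6 h)
#' or `shifted_ge6` (>= 6 h).
#'
#' @param peaks_a,peaks_b Tibbles with `gene_id` and `peak_label` (from
#'   [peak_times()]) for the two sites.
#' @param genes Optional gene ids restricting the comparison (e.g. the
#'   cross-site detected set).
#' @param daylight_a,daylight_b Light-period lengths used to place labels
#'   on the sunrise-anchored clock.
#' @return Tibble with `gene_id`, `peak_a`, `peak_b`, `shift_hours`,
#'   `category`.
#' @export
peak_shift_table <- function(peaks_a, peaks_b, genes = NULL,
                             daylight_a = 12, daylight_b = 12) {
  joined <- dplyr::inner_join(
    dplyr::select(peaks_a, "gene_id", peak_a = "peak_label"),
    dplyr::select(peaks_b, "gene_id", peak_b = "peak_label"),
    by = "gene_id"
  )
  if (!is.null(genes)) {
    joined <- dplyr::filter(joined, .data$gene_id %in% genes)
  }
  ha <- label_phase_hours(collapse_label(joined$peak_a), daylight_a)
  hb <- label_phase_hours(collapse_label(joined$peak_b), daylight_b)
  shift <- circular_shift(ha, hb)
  joined |>
    dplyr::mutate(
      shift_hours = shift,
      category = dplyr::case_when(
        shift == 0 ~ "maintained",
        shift < 6 ~ "shifted_lt6",
        TRUE ~ "shifted_ge6"
      )
    )
}

#' Minimal circular distance on a 24 h clock
#'
#' @param a,b Hours in `[0, 24)`.
#' @return Distances in `[0, 12]`.
#' @export
circular_shift <- function(a, b) {
  d <- abs(a - b) %% 24
  pmin(d, 24 - d)
}
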