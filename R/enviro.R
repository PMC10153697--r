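#' Mixed-layer depth from a density profile
#'
#' The mixed-layer depth is the shallowest pressure at which potential
#' density sigma-theta first reaches its value at the reference pressure
#' plus `offset`, linearly interpolated between the bounding records. If
#' the threshold is never reached the deepest pressure is returned with a
#' `reached = FALSE` flag.
#'
#' @param profile Tibble (or data frame) with `pressure` (dbar) and
#'   `sigma_theta` (kg/m3); must cover `ref_pressure`.
#' @param offset Density offset defining the mixed layer (kg/m3).
#' @param ref_pressure Reference pressure (dbar).
#' @return Tibble with `mld` (dbar) and logical `reached`.
#' @export
mld_from_ctd <- function(profile, offset = 0.03, ref_pressure = 10) {
  stopifnot(all(is.finite(profile$sigma_theta)))
  prof <- profile[order(profile$pressure), ]
  if (min(prof$pressure) > ref_pressure ||
      max(prof$pressure) < ref_pressure) {
    stop("profile does not cover the reference pressure", call. = FALSE)
  }
  sigma_ref <- stats::approx(prof$pressure, prof$sigma_theta,
                             xout = ref_pressure)$y
  target <- sigma_ref + offset
  below <- prof$pressure >= ref_pressure
  p <- prof$pressure[below]
  s <- prof$sigma_theta[below]
  idx <- which(s >= target)
  if (length(idx) == 0) {
    return(tibble::tibble(mld = max(p), reached = FALSE))
  }
  i <- idx[1]
  if (i == 1 || s[i] == target) {
    return(tibble::tibble(mld = p[i], reached = TRUE))
  }
  frac <- (target - s[i - 1]) / (s[i] - s[i - 1])
  tibble::tibble(mld = p[i - 1] + frac * (p[i] - p[i - 1]), reached = TRUE)
}

#' Non-metric multidimensional scaling of transcript profiles
#'
#' Two-dimensional NMDS minimizing Kruskal stress by iterative monotone
#' regression from multiple random starts (via `vegan::metaMDS` without
#' any community-data transformation). Points are typically genes, with
#' samples as coordinates of the input matrix.
#'
#' @param points Numeric matrix or wide tibble (rows = points).
#' @param distance Dissimilarity index (default `"euclidean"`).
#' @param dims Ordination dimensionality.
#' @param n_starts Random starts.
#' @param seed Integer seed.
#' @return Object of class `ordination`: `coords` tibble (`id`, `axis1`,
#'   `axis2`), `stress` (Kruskal stress-1, in `[0, 1]`), `seed`, and the
#'   underlying `metaMDS` fit.
#' @export
nmds <- function(points, distance = "euclidean", dims = 2, n_starts = 20,
                 seed = 1L) {
  m <- if (is.data.frame(points)) expr_to_matrix(points) else points
  if (nrow(m) < 4) stop("need >= 4 points for NMDS", call. = FALSE)
  if (max(vegan::vegdist(m, method = distance)) == 0) {
    # all points identical: the trivial zero-stress embedding
    return(structure(
      list(coords = tibble::tibble(id = rownames(m), axis1 = 0,
                                   axis2 = 0),
           stress = 0, seed = seed, fit = NULL),
      class = "ordination"
    ))
  }
  fit <- withr::with_seed(seed, suppressWarnings(suppressMessages(
    vegan::metaMDS(m, distance = distance, k = dims, try = n_starts,
                   trymax = n_starts, autotransform = FALSE,
                   wascores = FALSE, trace = 0)
  )))
  sc <- vegan::scores(fit, display = "sites")
  structure(
    list(coords = tibble::tibble(id = rownames(m),
                                 axis1 = sc[, 1], axis2 = sc[, 2]),
         stress = fit$stress, seed = seed, fit = fit),
    class = "ordination"
  )
}

#' @export
print.ordination <- function(x, ...) {
  cat("<ordination> ", nrow(x$coords), " points, stress = ",
      format(x$stress, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Fit environmental vectors onto an ordination
#'
#' For each environmental variable, the centered values are regressed on
#' the 2-D ordination coordinates (via `vegan::envfit`); `r_squared` is the
#' squared multiple correlation and the permutation p-value is
#' `(1 + #permuted r2 >= observed) / (n_perm + 1)`.
#'
#' @param ord An `ordination` (or a 2-column coordinate matrix).
#' @param env Tibble/data frame of environmental variables, rows aligned
#'   to the ordination points; every variable must be non-constant.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return Tibble with `variable`, `axis1`, `axis2` (direction cosines),
#'   `r_squared`, `p`, `significant` (p < 0.05).
#' @export
envfit_vectors <- function(ord, env, n_perm = 999, seed = 1L) {
  coords <- if (inherits(ord, "ordination")) {
    as.matrix(ord$coords[c("axis1", "axis2")])
  } else {
    as.matrix(ord)
  }
  env <- as.data.frame(env)
  constant <- vapply(env, function(v) sd(v) == 0, logical(1))
  if (any(constant)) {
    stop("constant environmental variable(s): ",
         paste(names(env)[constant], collapse = ", "), call. = FALSE)
  }
  fit <- withr::with_seed(seed,
    vegan::envfit(coords, env, permutations = n_perm)
  )
  arrows <- fit$vectors$arrows
  tibble::tibble(
    variable = rownames(arrows),
    axis1 = arrows[, 1], axis2 = arrows[, 2],
    r_squared = unname(fit$vectors$r),
    p = unname(fit$vectors$pvals),
    significant = unname(fit$vectors$pvals) < 0.05
  )
}

#' Per-gene environmental values for a gene-point ordination
#'
#' When ordination points are genes, environmental variables must be
#' summarized per gene before vector fitting. The default summary is the
#' Pearson correlation of the gene's expression series (replicate-averaged
#' onto the cast time grid) with the variable's series over casts.
#'
#' @param expr Wide gene expression tibble.
#' @param design Matching design tibble.
#' @param ctd CTD tibble from [simulate_ctd()] or a reader (one cast per
#'   time point, with `hours_since_start` and variable columns).
#' @param variables Which CTD columns to use; defaults to all numeric
#'   columns except positional ones.
#' @return Tibble: `gene_id` plus one column per variable.
#' @export
gene_env_values <- function(expr, design, ctd, variables = NULL) {
  if (is.null(variables)) {
    skip <- c("cast_id", "clock_hour", "hours_since_start", "pressure")
    variables <- setdiff(names(ctd)[vapply(ctd, is.numeric, logical(1))],
                         skip)
  }
  avg <- average_replicates(expr, design)
  ctd <- ctd[order(ctd$hours_since_start), ]
  stopifnot(nrow(ctd) == length(avg$t))
  out <- tibble::tibble(gene_id = rownames(avg$m))
  for (v in variables) {
    out[[v]] <- unname(suppressWarnings(
      apply(avg$m, 1, function(row) cor(row, ctd[[v]]))
    ))
  }
  out
}

#' Gene-environment correlations with group medians
#'
#' Pearson correlation of each gene's (replicate-averaged) series with
#' each environmental variable, plus group medians (e.g. diel/non-diel by
#' sublineage).
#'
#' @inheritParams gene_env_values
#' @param groups Optional tibble with `gene_id` and grouping columns
#'   (e.g. `is_diel`, `sublineage`).
#' @return List with `per_gene` (long tibble: `gene_id`, `variable`,
#'   `rho`) and `group_medians` (or `NULL` when `groups` is missing).
#' @export
env_gene_correlations <- function(expr, design, ctd, variables = NULL,
                                  groups = NULL) {
  vals <- gene_env_values(expr, design, ctd, variables)
  per_gene <- tidyr::pivot_longer(vals, -"gene_id",
                                  names_to = "variable",
                                  values_to = "rho")
  group_medians <- NULL
  if (!is.null(groups)) {
    group_medians <- per_gene |>
      dplyr::inner_join(groups, by = "gene_id") |>
      dplyr::group_by(dplyr::across(-c("gene_id", "rho"))) |>
      dplyr::summarise(median_rho = median(.data$rho, na.rm = TRUE),
                       n = dplyr::n(), .groups = "drop")
  }
  list(per_gene = per_gene, group_medians = group_medians)
}

#' Read a CTD table
#'
#' @param path CSV with columns `cast_id`, `pressure` and measurement
#'   variables (and optionally `clock_hour` / `hours_since_start`).
#' @return Tibble.
#' @export
read_ctd <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
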