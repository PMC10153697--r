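# member sets (as sorted id strings) for every internal node of an hclust
node_sets <- function(hc, ids) {
  n <- length(ids)
  members <- vector("list", nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    take <- function(j) if (j < 0) ids[-j] else members[[j]]
    members[[k]] <- sort(c(take(hc$merge[k, 1]), take(hc$merge[k, 2])))
  }
  members
}

# 1 - Pearson correlation distance between rows; NA correlations
# (zero-variance rows under resampling) are treated as no correlation
cor_dist <- function(m) {
  cc <- suppressWarnings(cor(t(m)))
  cc[!is.finite(cc)] <- 0
  stats::as.dist(1 - cc)
}

#' Hierarchical clustering with bootstrap support
#'
#' Clusters rows of a profile matrix by `1 - Pearson` correlation distance
#' and the given linkage, then measures support for every internal node as
#' the fraction of column (time point / sample) bootstrap resamples whose
#' re-clustering reproduces exactly that node's member set. Reported
#' clusters are the maximal nodes (excluding the root) with support at
#' least `alpha`; each row is assigned to the largest such cluster that
#' contains it.
#'
#' @param profiles Numeric matrix (rows = items to cluster, e.g.
#'   standardized diel gene profiles) or a wide tibble with an id column.
#' @param n_boot Number of bootstrap resamples of the columns.
#' @param alpha Minimum support for a reported cluster.
#' @param linkage `hclust` linkage method (`"centroid"` for diel profiles,
#'   `"average"` for pathway columns).
#' @param seed Integer seed.
#' @return List of class `boot_clust`: `assignments` (tibble `id`,
#'   `cluster_id`), `clusters` (tibble `cluster_id`, `size`, `support`),
#'   `hclust`, and per-node `node_support`.
#' @export
cluster_profiles_boot <- function(profiles, n_boot = 1000, alpha = 0.95,
                                  linkage = "centroid", seed = 1L) {
  m <- if (is.data.frame(profiles)) expr_to_matrix(profiles) else profiles
  if (nrow(m) < 2) stop("need >= 2 profiles to cluster", call. = FALSE)
  ids <- rownames(m)
  d <- cor_dist(m)
  if (max(d) == 0) {
    # all profiles identical: one cluster, trivially supported
    return(structure(list(
      assignments = tibble::tibble(id = ids, cluster_id = "k1"),
      clusters = tibble::tibble(cluster_id = "k1", size = nrow(m),
                                support = 1),
      hclust = NULL, node_support = numeric(0)
    ), class = "boot_clust"))
  }
  hc <- stats::hclust(d, method = linkage)
  sets <- node_sets(hc, ids)
  keys <- vapply(sets, paste, character(1), collapse = "\r")
  hits <- setNames(numeric(length(keys)), keys)
  withr::with_seed(seed, {
    for (b in seq_len(n_boot)) {
      cols <- sample(ncol(m), replace = TRUE)
      hb <- stats::hclust(cor_dist(m[, cols, drop = FALSE]),
                          method = linkage)
      kb <- vapply(node_sets(hb, ids), paste, character(1),
                   collapse = "\r")
      seen <- intersect(unique(kb), keys)
      hits[seen] <- hits[seen] + 1
    }
  })
  support <- hits / n_boot
  n_node <- length(sets)
  sig <- which(support >= alpha)
  sig <- setdiff(sig, n_node)  # root holds everything; not a cluster
  # maximal significant nodes: not contained in a larger significant one
  sizes <- vapply(sets, length, integer(1))
  sig <- sig[order(-sizes[sig])]
  maximal <- integer(0)
  covered <- character(0)
  for (k in sig) {
    if (!any(sets[[k]] %in% covered)) {
      maximal <- c(maximal, k)
      covered <- c(covered, sets[[k]])
    }
  }
  assignments <- tibble::tibble(id = ids, cluster_id = NA_character_)
  clusters <- tibble::tibble(cluster_id = character(0), size = integer(0),
                             support = numeric(0))
  for (i in seq_along(maximal)) {
    cid <- paste0("k", i)
    assignments$cluster_id[assignments$id %in% sets[[maximal[i]]]] <- cid
    clusters <- dplyr::bind_rows(clusters, tibble::tibble(
      cluster_id = cid, size = sizes[maximal[i]],
      support = unname(support[maximal[i]])
    ))
  }
  structure(list(assignments = assignments, clusters = clusters,
                 hclust = hc, node_support = support),
            class = "boot_clust")
}

#' @export
print.boot_clust <- function(x, ...) {
  cat("<boot_clust> ", nrow(x$clusters), " supported cluster(s) over ",
      nrow(x$assignments), " items\n", sep = "")
  if (nrow(x$clusters) > 0) print(x$clusters)
  invisible(x)
}

#' Cluster standardized diel gene profiles
#'
#' Standardizes each diel gene's series, then clusters genes with
#' correlation-based distances, centroid linkage and bootstrap support over
#' resampled time points. Typical studies recover a sunrise-peaking and a
#' sunset-peaking cluster.
#'
#' @param expr Wide expression tibble restricted to diel genes.
#' @param design Matching design tibble.
#' @param n_boot,alpha,seed See [cluster_profiles_boot()].
#' @return A `boot_clust` whose assignment ids are gene ids.
#' @export
cluster_diel_profiles <- function(expr, design, n_boot = 1000,
                                  alpha = 0.95, seed = 1L) {
  avg <- average_replicates(expr, design)
  m <- t(apply(avg$m, 1, standardize_series))
  rownames(m) <- rownames(avg$m)
  cluster_profiles_boot(m, n_boot = n_boot, alpha = alpha,
                        linkage = "centroid", seed = seed)
}
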