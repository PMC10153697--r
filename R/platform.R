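#' Load an array platform design
#'
#' Joins a probe annotation table with probe sequences from a FASTA file and
#' validates that the two agree.
#'
#' @param annotation Path to a TSV with columns `probe_id`, `gene_id`,
#'   `sublineage` and optionally `pathway`, `gene_symbol` — or a tibble with
#'   those columns.
#' @param sequences Optional path to a probe FASTA; sequences are attached
#'   by probe id. Probes present in the FASTA but absent from the
#'   annotation are an error.
#' @param ercc_ids Optional character vector of spike-in control ids.
#' @param replicate_spots Number of times each probe is replicated on the
#'   physical array (>= 1).
#' @return A list of class `platform_design` with elements `probes`
#'   (tibble), `ercc_ids`, `replicate_spots`, and `sublineage_counts`.
#' @export
parse_platform <- function(annotation, sequences = NULL,
                           ercc_ids = character(0), replicate_spots = 4L) {
  ann <- if (is.character(annotation)) {
    readr::read_tsv(annotation, show_col_types = FALSE)
  } else {
    tibble::as_tibble(annotation)
  }
  if (nrow(ann) == 0) stop("empty platform annotation", call. = FALSE)
  req <- c("probe_id", "gene_id", "sublineage")
  miss <- setdiff(req, names(ann))
  if (length(miss) > 0) {
    stop("annotation lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(ann$probe_id)) {
    stop("duplicated probe ids in annotation", call. = FALSE)
  }
  stopifnot(replicate_spots >= 1)
  if (!is.null(sequences)) {
    seqs <- read_fasta_tbl(sequences)
    orphan <- setdiff(seqs$id, ann$probe_id)
    if (length(orphan) > 0) {
      stop("probes in FASTA absent from annotation: ",
           paste(head(orphan, 10), collapse = ", "), call. = FALSE)
    }
    ann <- dplyr::left_join(ann,
                            dplyr::rename(seqs, probe_id = "id"),
                            by = "probe_id")
  }
  counts <- ann |>
    dplyr::count(.data$sublineage, name = "n_probes") |>
    dplyr::left_join(
      ann |> dplyr::distinct(.data$sublineage, .data$gene_id) |>
        dplyr::count(.data$sublineage, name = "n_genes"),
      by = "sublineage"
    )
  structure(
    list(probes = ann, ercc_ids = ercc_ids,
         replicate_spots = as.integer(replicate_spots),
         sublineage_counts = counts),
    class = "platform_design"
  )
}

#' @export
print.platform_design <- function(x, ...) {
  cat("<platform_design> ", nrow(x$probes), " probes, ",
      sum(x$sublineage_counts$n_genes), " genes, ",
      x$replicate_spots, " replicate spots/probe\n", sep = "")
  print(x$sublineage_counts)
  invisible(x)
}

# read a FASTA into tibble(id, sequence); Biostrings handles the format
read_fasta_tbl <- function(path) {
  if (is.data.frame(path)) {
    stopifnot(all(c("id", "sequence") %in% names(path) |
                    c("probe_id", "sequence") %in% names(path)))
    x <- tibble::as_tibble(path)
    if ("probe_id" %in% names(x)) x <- dplyr::rename(x, id = "probe_id")
    return(x[c("id", "sequence")])
  }
  ss <- Biostrings::readDNAStringSet(path)
  tibble::tibble(id = names(ss), sequence = as.character(ss))
}

# alignment identity / coverage with N treated as matching nothing
aln_stats <- function(pattern_aln, subject_aln, probe_len, probe_start,
                      probe_end) {
  p <- strsplit(pattern_aln, "")[[1]]
  s <- strsplit(subject_aln, "")[[1]]
  n_match <- sum(p == s & p != "-" & p != "N")
  span <- length(p)
  c(identity = 100 * n_match / span,
    coverage = 100 * (probe_end - probe_start + 1) / probe_len)
}

local_hit <- function(probe_seq, ref_seq) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(probe_seq), Biostrings::DNAString(ref_seq),
    type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 2, gapExtension = 2
  )
  st <- aln_stats(as.character(Biostrings::alignedPattern(aln)),
                  as.character(Biostrings::alignedSubject(aln)),
                  nchar(probe_seq),
                  Biostrings::start(Biostrings::pattern(aln)),
                  Biostrings::end(Biostrings::pattern(aln)))
  st
}

#' Screen probes for cross-hybridization
#'
#' Locally aligns every probe against every reference of a *different*
#' sublineage (both strands) and reports hits whose identity over the
#' alignment span and aligned fraction of the probe both reach the
#' thresholds. This emulates oligo-array hybridization specificity, where
#' a target within 5% mismatch over the whole probe can hybridize.
#' Thresholds are inclusive; gaps count as mismatches; `N` matches nothing.
#'
#' @param probes Tibble with `probe_id`, `sublineage`, `sequence` (and
#'   optionally `gene_id`).
#' @param references Tibble with `ref_id` (or `id`), `sublineage`,
#'   `sequence`.
#' @param identity_threshold Minimum percent identity (default 95).
#' @param length_threshold Minimum percent of the probe aligned
#'   (default 95).
#' @param strict If `TRUE`, thresholds are exclusive (`>`) instead of
#'   inclusive (`>=`).
#' @return Tibble of hits: `probe_id`, `ref_id`, `ref_sublineage`,
#'   `strand`, `percent_identity`, `aligned_fraction`.
#' @export
cross_hybridization_screen <- function(probes, references,
                                       identity_threshold = 95,
                                       length_threshold = 95,
                                       strict = FALSE) {
  if (nrow(references) == 0) stop("no reference sequences", call. = FALSE)
  if ("id" %in% names(references) && !"ref_id" %in% names(references)) {
    references <- dplyr::rename(references, ref_id = "id")
  }
  if (nrow(probes) == 0) {
    return(tibble::tibble(probe_id = character(0), ref_id = character(0),
                          ref_sublineage = character(0),
                          strand = character(0),
                          percent_identity = numeric(0),
                          aligned_fraction = numeric(0)))
  }
  pass <- if (strict) `>` else `>=`
  hits <- list()
  for (i in seq_len(nrow(probes))) {
    for (j in seq_len(nrow(references))) {
      if (probes$sublineage[i] == references$sublineage[j]) next
      for (strand in c("+", "-")) {
        ref <- references$sequence[j]
        if (strand == "-") {
          ref <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(ref)))
        }
        st <- local_hit(probes$sequence[i], ref)
        if (pass(st[["identity"]], identity_threshold) &&
            pass(st[["coverage"]], length_threshold)) {
          hits[[length(hits) + 1]] <- tibble::tibble(
            probe_id = probes$probe_id[i],
            ref_id = references$ref_id[j],
            ref_sublineage = references$sublineage[j],
            strand = strand,
            percent_identity = st[["identity"]],
            aligned_fraction = st[["coverage"]]
          )
        }
      }
    }
  }
  if (length(hits) == 0) {
    return(tibble::tibble(probe_id = character(0), ref_id = character(0),
                          ref_sublineage = character(0),
                          strand = character(0),
                          percent_identity = numeric(0),
                          aligned_fraction = numeric(0)))
  }
  dplyr::bind_rows(hits)
}

# pairwise global identity over the alignment span, gaps as mismatches
global_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE),
    gapOpening = 2, gapExtension = 2
  )
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  100 * sum(p == s & p != "-" & p != "N") / length(p)
}

#' Cluster probes by sequence identity
#'
#' Greedy length-sorted clustering in the style of CD-HIT: probes are
#' sorted by decreasing length (ties broken by id), and each probe joins
#' the first existing cluster whose representative it matches at or above
#' the identity threshold over the full alignment, otherwise it founds a
#' new cluster with itself as representative.
#'
#' @inheritParams cross_hybridization_screen
#' @return Tibble with `probe_id`, `gene_id`, `sublineage`, `gene_symbol`
#'   (if present), and `cluster_id`.
#' @export
cluster_probes <- function(probes, identity_threshold = 95) {
  ord <- order(-nchar(probes$sequence), probes$probe_id)
  probes <- probes[ord, ]
  reps <- character(0)
  cluster <- integer(nrow(probes))
  for (i in seq_len(nrow(probes))) {
    assigned <- NA_integer_
    for (k in seq_along(reps)) {
      if (global_identity(probes$sequence[i], reps[k]) >=
          identity_threshold) {
        assigned <- k
        break
      }
    }
    if (is.na(assigned)) {
      reps <- c(reps, probes$sequence[i])
      assigned <- length(reps)
    }
    cluster[i] <- assigned
  }
  probes$cluster_id <- sprintf("c%03d", cluster)
  keep <- intersect(c("probe_id", "gene_id", "sublineage", "gene_symbol",
                      "cluster_id"), names(probes))
  probes[keep]
}

#' Reject probes from ambiguous clusters
#'
#' A probe is rejected when its cluster spans multiple sublineages or
#' multiple genes, unless its gene symbol is whitelisted (e.g. probes for
#' highly conserved genes such as *nifH*).
#'
#' @param clusters Output of [cluster_probes()].
#' @param whitelist Gene symbols exempt from rejection.
#' @return Character vector of rejected probe ids.
#' @export
flag_ambiguous <- function(clusters, whitelist = character(0)) {
  amb <- clusters |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::summarise(
      n_sub = dplyr::n_distinct(.data$sublineage),
      n_gene = dplyr::n_distinct(.data$gene_id),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_sub > 1 | .data$n_gene > 1)
  bad <- clusters |>
    dplyr::filter(.data$cluster_id %in% amb$cluster_id)
  if ("gene_symbol" %in% names(bad) && length(whitelist) > 0) {
    bad <- dplyr::filter(bad, !(.data$gene_symbol %in% whitelist))
  }
  bad$probe_id
}

#' Probe-set coverage summary
#'
#' @param design A `platform_design` (or annotation tibble with `gene_id`).
#' @param k Probe-count threshold for the coverage fraction.
#' @return A list with `per_gene` (tibble `gene_id`, `n_probes`) and
#'   `fraction_ge_k`, the fraction of genes with at least `k` probes.
#' @export
probe_set_summary <- function(design, k = 3) {
  ann <- if (inherits(design, "platform_design")) design$probes else design
  if (is.null(ann) || nrow(ann) == 0) {
    return(list(per_gene = tibble::tibble(gene_id = character(0),
                                          n_probes = integer(0)),
                fraction_ge_k = NA_real_))
  }
  per_gene <- ann |> dplyr::count(.data$gene_id, name = "n_probes")
  list(per_gene = per_gene,
       fraction_ge_k = mean(per_gene$n_probes >= k))
}
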