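#' Default pipeline configuration
#'
#' A nested list describing one full synthetic study: the sampling design
#' (10 time points at 3 h intervals with duplicates, sunrise-anchored
#' labels), the gene truth table, probe expansion, the spike-in ladder,
#' and all stage thresholds (SNR > 5, spike floor exceeded in > 3 samples,
#' diel FDR < 0.25, 95% identity screening, pathway kept when detected in
#' more than a third of samples). The configuration round-trips losslessly
#' through YAML via [write_config()] / [read_config()].
#'
#' @param seed Master seed; every stage derives its own seed from it.
#' @return A config list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    design = list(n_timepoints = 10L, interval = 3, n_replicates = 2L,
                  sunrise_hour = 6, daylight = 12),
    genes = list(n_genes = 300L, prop_diel = 0.10, prop_low = 0.15,
                 amplitude = 1.5),
    noise_sd = 0.5,
    probes = list(probes_per_gene = c(4L, 6L), affinity_sd = 0.3),
    ercc = list(slope = 1, intercept = 3, noise_sd = 0.1),
    thresholds = list(snr = 5, ercc_min_samples = 3L, fdr = 0.25,
                      identity = 95, pathway_fraction = 1 / 3),
    diel = list(B = 200L),
    timepoint_subset = NULL,
    stages = list(detect = TRUE, diel = TRUE, compare = TRUE,
                  enviro = TRUE),
    cross_site = TRUE,
    coastal = list(n_timepoints = 8L, prop_diel = 0.85)
  )
}

#' Read and write pipeline configurations
#'
#' @param config A config list.
#' @param path YAML file path.
#' @return `read_config()` returns the config list; `write_config()`
#'   returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  # full double precision so thresholds like 1/3 round-trip losslessly
  yaml::write_yaml(config, path, precision = 17L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

# per-stage seeds derived from the master seed; kept below 2^31
stage_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 97L * k) %% 2147483629)
}

validate_config <- function(config) {
  th <- config$thresholds
  stopifnot(th$snr > 0, th$ercc_min_samples >= 0,
            th$fdr > 0, th$fdr <= 1,
            th$identity > 0, th$identity <= 100,
            th$pathway_fraction >= 0, th$pathway_fraction < 1,
            config$design$interval > 0, config$design$n_timepoints >= 4)
  invisible(config)
}

# one site: simulate -> normalize -> detect -> diel -> peaks
run_site <- function(design, truths, config, seed_base) {
  expr_true <- simulate_expression(design, truths,
                                   noise_sd = config$noise_sd,
                                   seed = stage_seed(seed_base, 1))
  pr <- expand_to_probes(expr_true,
                         probes_per_gene = config$probes$probes_per_gene,
                         affinity_sd = config$probes$affinity_sd,
                         truths = truths,
                         seed = stage_seed(seed_base, 2))
  spikes <- spike_ercc(design, slope = config$ercc$slope,
                       intercept = config$ercc$intercept,
                       noise_sd = config$ercc$noise_sd,
                       seed = stage_seed(seed_base, 3))
  norm <- quantile_normalize(pr$intensities)
  expr <- median_polish_summarize(norm, pr$platform)
  out <- list(design = design, truths = truths, expr = expr,
              platform = pr$platform, spikes = spikes)
  if (isTRUE(config$stages$detect)) {
    out$detection <- detect_genes(
      expr, spikes, snr_threshold = config$thresholds$snr,
      min_samples = config$thresholds$ercc_min_samples)
  }
  if (isTRUE(config$stages$diel)) {
    det_ids <- if (!is.null(out$detection)) detected_genes(out$detection)
               else expr$gene_id
    expr_det <- dplyr::filter(expr, .data$gene_id %in% det_ids)
    out$diel <- fdr_fourier(expr_det, design, B = config$diel$B,
                            fdr_threshold = config$thresholds$fdr,
                            seed = stage_seed(seed_base, 4))
    out$peaks <- peak_times(expr_det, design)
  }
  out
}

#' Run the full pipeline on synthetic data
#'
#' Generates a fixture study from the configuration and pushes it through
#' every stage: probe expansion, quantile normalization, median-polish
#' summarization, spike-in-calibrated detection, Fourier/AR1 diel calling
#' and peak times; optionally a second (coastal-style) site for the
#' cross-habitat statistics (detection overlap, Fisher's exact test of
#' diel status by habitat, peak-shift table), environmental covariates
#' (CTD correlations, mixed-layer depth) and a diel rerun on a time-point
#' subset. Identical configurations and seeds give identical bundles.
#'
#' @param config Config list from [default_config()] (possibly edited) or
#'   a YAML path.
#' @param out_dir Optional directory; when given, the bundle's tables are
#'   written as TSV files, each carrying the config hash in a header
#'   comment.
#' @return A list of class `diel_run` with the per-site results, the
#'   cross-site comparisons, the environmental stage, a `summary` tibble
#'   of headline counts, the `config` and its `hash`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  hash <- rlang::hash(config)
  seed <- config$seed
  with_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  design <- with_stage("design", do.call(make_design, config$design))
  truths <- with_stage("truths", make_gene_truth(
    n_genes = config$genes$n_genes, prop_diel = config$genes$prop_diel,
    prop_low = config$genes$prop_low, amplitude = config$genes$amplitude,
    seed = stage_seed(seed, 10)))
  site_a <- with_stage("site_a", run_site(design, truths, config, seed))
  out <- list(config = config, hash = hash, site_a = site_a)

  if (isTRUE(config$cross_site) && isTRUE(config$stages$compare)) {
    design_b <- with_stage("design_b", make_design(
      config$coastal$n_timepoints, config$design$interval,
      config$design$n_replicates, config$design$sunrise_hour,
      config$design$daylight))
    truths_b <- with_stage("truths_b", make_gene_truth(
      n_genes = config$genes$n_genes,
      prop_diel = config$coastal$prop_diel,
      prop_low = config$genes$prop_low,
      amplitude = config$genes$amplitude,
      seed = stage_seed(seed, 11)))
    site_b <- with_stage("site_b",
                         run_site(design_b, truths_b, config,
                                  stage_seed(seed, 20)))
    out$site_b <- site_b
    out$compare <- with_stage("compare", {
      ov <- detection_overlap(site_a$detection, site_b$detection)
      diel_a <- site_a$diel$results
      diel_b <- site_b$diel$results
      shared <- ov$both
      tab <- matrix(c(
        sum(shared %in% diel_a$gene_id[!diel_a$is_diel]),
        sum(shared %in% diel_a$gene_id[diel_a$is_diel]),
        sum(shared %in% diel_b$gene_id[!diel_b$is_diel]),
        sum(shared %in% diel_b$gene_id[diel_b$is_diel])
      ), nrow = 2, byrow = TRUE,
      dimnames = list(c("site_a", "site_b"), c("non_diel", "diel")))
      list(
        overlap = ov,
        habitat_table = tab,
        fisher = fisher_habitat_test(tab),
        peak_shifts = peak_shift_table(
          site_a$peaks, site_b$peaks, genes = shared,
          daylight_a = config$design$daylight,
          daylight_b = config$design$daylight)
      )
    })
  }

  if (isTRUE(config$stages$enviro)) {
    out$enviro <- with_stage("enviro", {
      ctd <- simulate_ctd(design)
      diel_ids <- site_a$diel$results$gene_id[site_a$diel$results$is_diel]
      groups <- dplyr::select(truths, "gene_id", "sublineage") |>
        dplyr::mutate(diel = .data$gene_id %in% diel_ids)
      corr <- env_gene_correlations(site_a$expr, design, ctd,
                                    groups = groups)
      profile <- simulate_density_profile()
      list(ctd = ctd, correlations = corr,
           mld = mld_from_ctd(profile))
    })
  }

  if (!is.null(config$timepoint_subset)) {
    out$diel_subset <- with_stage("diel_subset", {
      sub_design <- subset_timepoints(design, config$timepoint_subset)
      det_ids <- detected_genes(site_a$detection)
      expr_det <- dplyr::filter(site_a$expr,
                                .data$gene_id %in% det_ids)
      expr_sub <- expr_det[c("gene_id", sub_design$sample_id)]
      fdr_fourier(expr_sub, sub_design, B = config$diel$B,
                  fdr_threshold = config$thresholds$fdr,
                  seed = stage_seed(seed, 30))
    })
  }

  out$summary <- run_summary(out)
  class(out) <- "diel_run"
  if (!is.null(out_dir)) write_bundle(out, out_dir)
  out
}

run_summary <- function(out) {
  s <- tibble::tibble(
    quantity = "n_genes",
    value = nrow(out$site_a$truths)
  )
  add <- function(s, q, v) {
    dplyr::bind_rows(s, tibble::tibble(quantity = q, value = as.numeric(v)))
  }
  if (!is.null(out$site_a$detection)) {
    s <- add(s, "site_a_detected",
             sum(out$site_a$detection$per_gene$detected))
  }
  if (!is.null(out$site_a$diel)) {
    s <- add(s, "site_a_diel", sum(out$site_a$diel$results$is_diel))
  }
  if (!is.null(out$site_b)) {
    s <- add(s, "site_b_detected",
             sum(out$site_b$detection$per_gene$detected))
    s <- add(s, "site_b_diel", sum(out$site_b$diel$results$is_diel))
  }
  if (!is.null(out$compare)) {
    s <- add(s, "cross_site_detected", length(out$compare$overlap$both))
    s <- add(s, "fisher_p", out$compare$fisher$p)
    s <- add(s, "frac_shift_ge6",
             mean(out$compare$peak_shifts$category == "shifted_ge6"))
  }
  if (!is.null(out$diel_subset)) {
    s <- add(s, "site_a_diel_subset",
             sum(out$diel_subset$results$is_diel))
  }
  if (!is.null(out$enviro)) {
    s <- add(s, "mld", out$enviro$mld$mld)
  }
  s
}

#' @export
print.diel_run <- function(x, ...) {
  cat("<diel_run> config hash ", x$hash, "\n", sep = "")
  print(x$summary, n = Inf)
  invisible(x)
}

# write every tabular output as TSV with the config hash in a header line
write_bundle <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- paste0("# config_hash: ", run$hash)
  wr <- function(tbl, name) {
    path <- file.path(dir, name)
    writeLines(hdr, path)
    readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE)
  }
  wr(run$summary, "summary.tsv")
  wr(run$site_a$detection$per_gene, "site_a_detection.tsv")
  wr(run$site_a$diel$results, "site_a_diel.tsv")
  wr(run$site_a$peaks, "site_a_peaks.tsv")
  if (!is.null(run$site_b)) {
    wr(run$site_b$detection$per_gene, "site_b_detection.tsv")
    wr(run$site_b$diel$results, "site_b_diel.tsv")
    wr(run$compare$peak_shifts, "peak_shifts.tsv")
  }
  if (!is.null(run$diel_subset)) {
    wr(run$diel_subset$results, "site_a_diel_subset.tsv")
  }
  if (!is.null(run$enviro)) {
    wr(run$enviro$correlations$per_gene, "env_gene_correlations.tsv")
  }
  write_config(run$config, file.path(dir, "config.yaml"))
  invisible(dir)
}
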