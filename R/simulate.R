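#' Ground-truth gene table for synthetic fixtures
#'
#' Draws per-gene truth labels used by [simulate_expression()] and by
#' downstream recovery tests: which genes are diel, their peak phase and
#' amplitude, baseline level, AR1 autocorrelation of their noise, and
#' whether their baseline puts them above the detection floor.
#'
#' Defaults emulate an open-ocean diel study: a modest diel subpopulation
#' (about 10% of genes), log2 baselines centred near 8 with a low-intensity
#' tail that should fall below the noise floor, diel amplitudes of 1.5 log2
#' units and mildly autocorrelated noise.
#'
#' @param n_genes Number of genes.
#' @param prop_diel Fraction of genes that are diel.
#' @param prop_low Fraction of genes given low baselines (undetectable).
#' @param amplitude Diel amplitude in log2 units (single value or vector).
#' @param baseline_mean,baseline_sd Normal parameters of detectable
#'   baselines (log2).
#' @param low_baseline Baseline for the undetectable subpopulation (log2).
#' @param ar1_phi Lag-1 autocorrelation of each gene's noise process.
#' @param sublineages Sublineage labels to assign (recycled at random).
#' @param pathways Pathway labels to assign (recycled at random).
#' @param seed Integer seed; fixed seed gives identical tables.
#' @return A tibble with columns `gene_id`, `sublineage`, `pathway`,
#'   `is_diel`, `peak_phase`, `amplitude`, `baseline`, `ar1_phi`,
#'   `detectable`.
#' @export
make_gene_truth <- function(n_genes, prop_diel = 0.10, prop_low = 0.15,
                            amplitude = 1.5, baseline_mean = 8,
                            baseline_sd = 1, low_baseline = 2,
                            ar1_phi = 0.2,
                            sublineages = c("A1", "A2", "A3"),
                            pathways = c("photosynthesis", "N2_fixation",
                                         "ATP_synthase", "ribosome",
                                         "transport", "other"),
                            seed = 1L) {
  stopifnot(n_genes >= 1, prop_diel >= 0, prop_diel <= 1,
            prop_low >= 0, prop_low + prop_diel <= 1)
  withr::with_seed(seed, {
    n_diel <- round(prop_diel * n_genes)
    n_low <- round(prop_low * n_genes)
    status <- sample(rep(c("diel", "low", "flat"),
                         c(n_diel, n_low, n_genes - n_diel - n_low)))
    tibble::tibble(
      gene_id = sprintf("g%05d", seq_len(n_genes)),
      sublineage = sample(sublineages, n_genes, replace = TRUE),
      pathway = sample(pathways, n_genes, replace = TRUE),
      is_diel = status == "diel",
      peak_phase = ifelse(status == "diel", runif(n_genes, 0, 24), NA_real_),
      amplitude = ifelse(status == "diel", amplitude, 0),
      baseline = ifelse(status == "low", low_baseline,
                        rnorm(n_genes, baseline_mean, baseline_sd)),
      ar1_phi = rep_len(ar1_phi, n_genes),
      detectable = status != "low"
    )
  })
}

# AR1 noise matrix (n series x n_t), stationary initialization
ar1_noise <- function(n, n_t, phi, innovation_sd) {
  phi <- rep_len(phi, n)
  x <- matrix(0, n, n_t)
  if (n_t == 0 || innovation_sd == 0) return(x)
  x[, 1] <- rnorm(n, 0, innovation_sd / sqrt(1 - phi^2))
  if (n_t > 1) {
    for (t in 2:n_t) {
      x[, t] <- phi * x[, t - 1] + rnorm(n, 0, innovation_sd)
    }
  }
  x
}

#' Simulate a gene-level diel expression matrix
#'
#' Diel genes follow `baseline + amplitude * cos(2*pi*(t - peak_phase)/24)`
#' at each sample's clock hour, plus AR1(`phi`) noise with the given
#' innovation standard deviation; non-diel genes are baseline plus the same
#' noise process. Replicate series at the same time points get independent
#' noise. Identical seeds give identical output.
#'
#' @param design Design tibble from [make_design()].
#' @param truths Truth tibble from [make_gene_truth()].
#' @param noise_sd AR1 innovation standard deviation, log2 units (>= 0).
#' @param seed Integer seed.
#' @return A wide tibble: `gene_id` plus one log2 column per `sample_id`,
#'   columns in design order.
#' @export
simulate_expression <- function(design, truths, noise_sd = 0.5, seed = 1L) {
  if (is.null(design) || nrow(design) == 0) {
    stop("`design` must contain at least one sample", call. = FALSE)
  }
  stopifnot(noise_sd >= 0)
  n_g <- nrow(truths)
  signal <- outer(
    seq_len(n_g), seq_len(nrow(design)),
    function(i, j) {
      amp <- ifelse(truths$is_diel[i], truths$amplitude[i], 0)
      ph <- ifelse(truths$is_diel[i], truths$peak_phase[i], 0)
      truths$baseline[i] +
        amp * cos(2 * pi * (design$clock_hour[j] - ph) / 24)
    }
  )
  noise <- matrix(0, n_g, nrow(design))
  withr::with_seed(seed, {
    for (r in sort(unique(design$replicate))) {
      idx <- which(design$replicate == r)
      idx <- idx[order(design$hours_since_start[idx])]
      noise[, idx] <- ar1_noise(n_g, length(idx), truths$ar1_phi, noise_sd)
    }
  })
  m <- signal + noise
  colnames(m) <- design$sample_id
  dplyr::bind_cols(tibble::tibble(gene_id = truths$gene_id),
                   tibble::as_tibble(m))
}

#' Expand a gene matrix to probe-level intensities
#'
#' Each gene gets a random number of probes in `probes_per_gene`; each probe
#' carries a fixed affinity offset (drawn once, constant across samples, as
#' the additive probe-effect model behind median polish assumes) and
#' optional per-cell noise. Probe intensity is
#' `2^(gene log2 level + affinity + noise)`, so values are linear scale and
#' strictly positive.
#'
#' @param expr Wide gene expression tibble (log2), from
#'   [simulate_expression()].
#' @param probes_per_gene Length-1 or length-2 integer vector giving the
#'   probe-set size or its inclusive range; all values in `[1, 10]`.
#' @param affinity_sd SD of the per-probe affinity offsets (log2 units).
#' @param probe_noise_sd SD of independent per-cell noise (log2 units).
#' @param truths Optional truth/annotation tibble with `gene_id`,
#'   `sublineage`, `pathway`; used to fill the platform annotation.
#' @param seed Integer seed.
#' @return A list with `intensities` (tibble: `probe_id` plus linear-scale
#'   sample columns) and `platform` (tibble: `probe_id`, `gene_id`,
#'   `sublineage`, `pathway`, `gene_symbol`).
#' @export
expand_to_probes <- function(expr, probes_per_gene = c(4L, 6L),
                             affinity_sd = 0.3, probe_noise_sd = 0,
                             truths = NULL, seed = 1L) {
  rng <- range(probes_per_gene)
  if (rng[1] < 1 || rng[2] > 10) {
    stop("`probes_per_gene` must lie within [1, 10]", call. = FALSE)
  }
  m <- expr_to_matrix(expr)
  n_g <- nrow(m)
  withr::with_seed(seed, {
    k <- if (rng[1] == rng[2]) rep(rng[1], n_g) else
      sample(seq(rng[1], rng[2]), n_g, replace = TRUE)
    gene_row <- rep(seq_len(n_g), k)
    affinity <- rnorm(sum(k), 0, affinity_sd)
    probe_log2 <- m[gene_row, , drop = FALSE] + affinity
    if (probe_noise_sd > 0) {
      probe_log2 <- probe_log2 +
        matrix(rnorm(length(probe_log2), 0, probe_noise_sd),
               nrow(probe_log2))
    }
  })
  probe_id <- paste0(rownames(m)[gene_row], "_p",
                     unlist(lapply(k, seq_len)))
  intensities <- dplyr::bind_cols(
    tibble::tibble(probe_id = probe_id),
    tibble::as_tibble(2^probe_log2)
  )
  ann <- tibble::tibble(probe_id = probe_id,
                        gene_id = rownames(m)[gene_row])
  if (!is.null(truths)) {
    ann <- dplyr::left_join(
      ann,
      dplyr::select(truths, "gene_id", "sublineage", "pathway"),
      by = "gene_id"
    )
  } else {
    ann$sublineage <- "A1"
    ann$pathway <- NA_character_
  }
  ann$gene_symbol <- ann$gene_id
  list(intensities = intensities, platform = ann)
}

#' Default synthetic spike-in ladder
#'
#' A two-fold concentration ladder (attomolar) whose least concentrated
#' member plays the role of the detection-bounding spike.
#'
#' @param n Number of spikes.
#' @param min_conc Concentration of the least concentrated spike (aM).
#' @return Tibble with `ercc_id` and `concentration`.
#' @export
default_ercc_ladder <- function(n = 8, min_conc = 4.7 / 4) {
  tibble::tibble(
    ercc_id = sprintf("ERCC-SYN-%02d", seq_len(n)),
    concentration = min_conc * 2^(seq_len(n) - 1)
  )
}

#' Simulate spike-in intensities
#'
#' Per sample, each spike's log2 intensity is
#' `intercept + slope * log2(concentration)` plus Gaussian noise. The
#' minimum-concentration member is flagged as the detection bound.
#'
#' @param design Design tibble.
#' @param ladder Tibble with `ercc_id` and distinct positive
#'   `concentration` (aM).
#' @param slope,intercept Calibration line on the log2-log2 scale.
#' @param noise_sd SD of log2 noise.
#' @param seed Integer seed.
#' @return Long tibble: `ercc_id`, `concentration`, `sample_id`,
#'   `intensity` (linear), `is_min` flag.
#' @export
spike_ercc <- function(design, ladder = default_ercc_ladder(),
                       slope = 1, intercept = 3, noise_sd = 0, seed = 1L) {
  stopifnot(all(ladder$concentration > 0),
            !anyDuplicated(ladder$concentration))
  out <- tidyr::crossing(ladder, sample_id = design$sample_id) |>
    dplyr::arrange(match(.data$ercc_id, ladder$ercc_id),
                   match(.data$sample_id, design$sample_id))
  withr::with_seed(seed, {
    out$intensity <- 2^(intercept + slope * log2(out$concentration) +
                          rnorm(nrow(out), 0, noise_sd))
  })
  out$is_min <- out$concentration == min(ladder$concentration)
  out
}

#' Simulate diel CTD covariates
#'
#' One cast per time point; every variable is a 24 h sinusoid
#' `mean + amplitude * cos(2*pi*(clock_hour - peak_phase)/24)` evaluated at
#' the sample clock hours.
#'
#' @param design Design tibble.
#' @param params Tibble with `variable`, `mean`, `amplitude`, `peak_phase`.
#' @param pressure Sampling pressure recorded on each cast (dbar).
#' @return Wide tibble: `cast_id`, `clock_hour`, `hours_since_start`,
#'   `pressure`, one column per variable.
#' @export
simulate_ctd <- function(design, params = default_ctd_params(),
                         pressure = 45) {
  tp <- design |>
    dplyr::distinct(.data$hours_since_start, .data$clock_hour) |>
    dplyr::arrange(.data$hours_since_start)
  out <- tibble::tibble(
    cast_id = sprintf("cast%02d", seq_len(nrow(tp))),
    clock_hour = tp$clock_hour,
    hours_since_start = tp$hours_since_start,
    pressure = pressure
  )
  for (i in seq_len(nrow(params))) {
    out[[params$variable[i]]] <- params$mean[i] +
      params$amplitude[i] *
        cos(2 * pi * (tp$clock_hour - params$peak_phase[i]) / 24)
  }
  out
}

#' @rdname simulate_ctd
#' @export
default_ctd_params <- function() {
  tibble::tribble(
    ~variable,      ~mean,  ~amplitude, ~peak_phase,
    "temperature",  24.0,   0.3,        15,
    "salinity",     35.2,   0.02,       12,
    "oxygen",       205,    3,          15,
    "chlorophyll",  0.08,   0.02,       13,
    "par",          10,     10,         12,
    "sigma_theta",  24.0,   0.02,       4
  )
}

#' Simulate a potential-density depth profile
#'
#' Builds a monotone non-decreasing sigma-theta profile: constant in the
#' mixed layer, then increasing linearly with pressure, arranged so the
#' profile crosses `sigma(ref) + offset` exactly at `mld_true`.
#'
#' @param surface_sigma Mixed-layer sigma-theta (kg/m3).
#' @param gradient Below-mixed-layer density gradient (kg/m3 per dbar, > 0).
#' @param mld_true Depth at which the offset threshold is crossed (dbar).
#' @param offset Density offset defining the mixed-layer depth (kg/m3).
#' @param max_pressure,step Grid of pressures sampled (dbar).
#' @return Tibble with `pressure` and `sigma_theta`.
#' @export
simulate_density_profile <- function(surface_sigma = 24, gradient = 0.01,
                                     mld_true = 28, offset = 0.03,
                                     max_pressure = 100, step = 1) {
  stopifnot(gradient > 0, mld_true > 10)
  p0 <- mld_true - offset / gradient
  stopifnot(p0 > 10)
  pressure <- seq(0, max_pressure, by = step)
  sigma <- surface_sigma + pmax(0, pressure - p0) * gradient
  tibble::tibble(pressure = pressure, sigma_theta = sigma)
}

#' Random probe and reference sequences for screening fixtures
#'
#' `simulate_probe_sequences()` draws independent random sequences for each
#' probe. `simulate_reference_sequences()` builds one synthetic reference
#' per sublineage by embedding that sublineage's probe sequences between
#' random spacers, so each probe has an exact match in its own reference.
#'
#' @param platform Annotation tibble with `probe_id`, `gene_id`,
#'   `sublineage`.
#' @param length Probe length in nucleotides.
#' @param seed Integer seed.
#' @return `simulate_probe_sequences()`: the platform tibble with a
#'   `sequence` column; `simulate_reference_sequences()`: a tibble with
#'   `ref_id`, `sublineage`, `sequence`.
#' @export
simulate_probe_sequences <- function(platform, length = 60, seed = 1L) {
  withr::with_seed(seed, {
    platform$sequence <- vapply(
      seq_len(nrow(platform)),
      function(i) paste(sample(c("A", "C", "G", "T"), length,
                               replace = TRUE), collapse = ""),
      character(1)
    )
  })
  platform
}

#' @param probe_seqs Output of [simulate_probe_sequences()].
#' @param spacer Length of random spacer between embedded probes.
#' @rdname simulate_probe_sequences
#' @export
simulate_reference_sequences <- function(probe_seqs, spacer = 30,
                                         seed = 1L) {
  withr::with_seed(seed, {
    subs <- sort(unique(probe_seqs$sublineage))
    purrr::map_dfr(subs, function(sl) {
      seqs <- probe_seqs$sequence[probe_seqs$sublineage == sl]
      spacers <- vapply(seq_len(length(seqs) + 1), function(i) {
        paste(sample(c("A", "C", "G", "T"), spacer, replace = TRUE),
              collapse = "")
      }, character(1))
      ref <- paste0(paste0(spacers[-length(spacers)], seqs,
                           collapse = ""), spacers[length(spacers)])
      tibble::tibble(ref_id = paste0("ref_", sl, "_synthetic"),
                     sublineage = sl, sequence = ref)
    })
  })
}

#' Write a fixture directory
#'
#' Writes the synthetic study to plain-text files under one directory:
#' probe intensities and platform annotation as TSV, design metadata and
#' gene truth as TSV, spike-ins as TSV, CTD records as CSV, probe and
#' reference sequences as FASTA, and a YAML manifest recording the
#' generator parameters.
#'
#' @param dir Output directory (created if needed).
#' @param design,truths,probes,platform,spikes,ctd Generator outputs; any
#'   may be `NULL` to skip.
#' @param probe_seqs,refs Optional sequence tibbles written as FASTA.
#' @param manifest Named list of parameters recorded in `manifest.yaml`.
#' @return Invisibly, the paths written.
#' @export
write_fixtures <- function(dir, design = NULL, truths = NULL, probes = NULL,
                           platform = NULL, spikes = NULL, ctd = NULL,
                           probe_seqs = NULL, refs = NULL,
                           manifest = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(x, name, fun) {
    if (is.null(x)) return()
    p <- file.path(dir, name)
    fun(x, p)
    paths[[length(paths) + 1]] <<- p
  }
  wr(design, "design.tsv", readr::write_tsv)
  wr(truths, "truth.tsv", readr::write_tsv)
  wr(probes, "probe_intensities.tsv", readr::write_tsv)
  wr(platform, "platform.tsv", readr::write_tsv)
  wr(spikes, "ercc_spikes.tsv", readr::write_tsv)
  wr(ctd, "ctd.csv", readr::write_csv)
  write_fa <- function(x, p) {
    ids <- if ("probe_id" %in% names(x)) x$probe_id else x$ref_id
    writeLines(paste0(">", ids, "\n", x$sequence), p)
  }
  wr(probe_seqs, "probe_sequences.fasta", write_fa)
  wr(refs, "reference_sequences.fasta", write_fa)
  p <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, p)
  paths[[length(paths) + 1]] <- p
  invisible(unlist(paths))
}

#' Convert between wide expression tibbles and matrices
#'
#' Wide tibbles have an id column (`gene_id`, `probe_id`, or `ercc_id`)
#' followed by one column per sample.
#'
#' @param x Wide tibble.
#' @return `expr_to_matrix()`: a numeric matrix with id rownames;
#'   `matrix_to_expr()`: a wide tibble.
#' @export
expr_to_matrix <- function(x) {
  id_col <- intersect(c("gene_id", "probe_id", "ercc_id"), names(x))[1]
  if (is.na(id_col)) stop("no id column found", call. = FALSE)
  m <- as.matrix(x[setdiff(names(x), id_col)])
  rownames(m) <- x[[id_col]]
  m
}

#' @param m Numeric matrix with rownames.
#' @param id_col Name of the id column to create.
#' @rdname expr_to_matrix
#' @export
matrix_to_expr <- function(m, id_col = "gene_id") {
  dplyr::bind_cols(tibble::tibble(!!id_col := rownames(m)),
                   tibble::as_tibble(m))
}
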