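# Brute-force oracles, independent of the package's implementations.

# Fourier score via complex exponentials
oracle_fourier <- function(x, t, period = 24) {
  Mod(sum(x * exp(-1i * 2 * pi * t / period)))
}

# Tukey median polish by explicit alternating sweeps (rows first), with
# the conventional stopping rule on the change in summed |residual|
oracle_medpolish_gene_levels <- function(block, max_iter = 10,
                                         eps = 0.01) {
  overall <- 0
  row_eff <- rep(0, nrow(block))
  col_eff <- rep(0, ncol(block))
  z <- block
  oldsum <- 0
  for (it in seq_len(max_iter)) {
    rdelta <- apply(z, 1, median)
    z <- sweep(z, 1, rdelta)
    row_eff <- row_eff + rdelta
    d <- median(col_eff)
    overall <- overall + d
    col_eff <- col_eff - d
    cdelta <- apply(z, 2, median)
    z <- sweep(z, 2, cdelta)
    col_eff <- col_eff + cdelta
    d <- median(row_eff)
    overall <- overall + d
    row_eff <- row_eff - d
    newsum <- sum(abs(z))
    if (newsum == 0 || abs(newsum - oldsum) < eps * newsum) break
    oldsum <- newsum
  }
  overall + col_eff
}

# quantile normalization: sort each column, average order statistics,
# place back by rank with tie groups sharing the mean reference value
oracle_quantile_normalize <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    o <- order(m[, j])
    vals <- ref
    # collapse ties to group means
    sorted <- m[o, j]
    g <- cumsum(c(TRUE, diff(sorted) != 0))
    vals <- stats::ave(ref, g)
    out[o, j] <- vals
  }
  out
}

# Welch statistic from the textbook formula
oracle_welch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# one-sided paired t from the textbook formula
oracle_paired_t <- function(a, b) {
  d <- a - b
  t <- mean(d) / (sd(d) / sqrt(length(d)))
  list(t = t, p = stats::pt(t, length(d) - 1, lower.tail = FALSE))
}

# two-sided Fisher p by full enumeration over tables with fixed margins
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(ks, r1, r2, c1)
  p_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Pearson on ranks (mean ranks for ties) = Spearman
oracle_spearman <- function(x, y) {
  cor(rank(x), rank(y))
}

# Hamming identity for equal-length sequences, N matches nothing
oracle_hamming_identity <- function(a, b) {
  pa <- strsplit(a, "")[[1]]
  pb <- strsplit(b, "")[[1]]
  stopifnot(length(pa) == length(pb))
  100 * sum(pa == pb & pa != "N") / length(pa)
}

# random DNA sequence
rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# mutate k distinct interior positions of a sequence
mutate_seq <- function(seq, positions) {
  ch <- strsplit(seq, "")[[1]]
  for (p in positions) {
    ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  }
  paste(ch, collapse = "")
}

# small standard study fixture shared across tests
small_study <- function(n_genes = 80, seed = 42, noise_sd = 0.4,
                        prop_diel = 0.2, amplitude = 1.5) {
  design <- make_design(10, 3, 2, sunrise_hour = 6, daylight = 12)
  truths <- make_gene_truth(n_genes, prop_diel = prop_diel,
                            amplitude = amplitude, seed = seed)
  expr <- simulate_expression(design, truths, noise_sd = noise_sd,
                              seed = seed + 1)
  list(design = design, truths = truths, expr = expr)
}
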