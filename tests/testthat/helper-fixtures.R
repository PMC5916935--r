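## Shared fixtures and independent oracles for the suite.

tiny_design <- function(...) {
  cohort_design(n_proteins = 8, peptides_per_protein = 2:4, seed = 11, ...)
}

## Deterministic, noise-free, fully observed design with one
## fraction-specific injected effect -- the controlled end-to-end case.
exact_design <- function(delta = 1, scope = "PHA", seed = 5) {
  cohort_design(
    n_proteins = 6, noise_sd = 0, missing_rate = 0, low_conf_rate = 0,
    cys_per_peptide = 1:2, seed = seed,
    effects = list(effect_spec("GENE0001", scope, delta_log2 = delta))
  )
}

## Closed-form Welch statistic, written independently of the package path.
welch_oracle <- function(x, y) {
  num <- mean(x) - mean(y)
  den <- sqrt(stats::var(x) / length(x) + stats::var(y) / length(y))
  if (den == 0) {
    if (num == 0) 0 else sign(num) * Inf
  } else {
    num / den
  }
}

## Brute-force exhaustive two-sided permutation p-value: explicit loop over
## every group relabeling, one t at a time.
brute_perm_p <- function(x, y) {
  z <- c(x, y)
  n <- length(z)
  nx <- length(x)
  cmb <- utils::combn(n, nx)
  t_obs <- abs(welch_oracle(x, y))
  thr <- if (is.infinite(t_obs)) t_obs else t_obs - 1e-8 * (1 + t_obs)
  hits <- 0L
  for (j in seq_len(ncol(cmb))) {
    idx <- cmb[, j]
    if (abs(welch_oracle(z[idx], z[-idx])) >= thr) hits <- hits + 1L
  }
  hits / ncol(cmb)
}

## Hand-built quantification rows on the normalized log2 scale.
make_quant <- function(gene, level, bph = numeric(0), pca = numeric(0)) {
  tibble::tibble(
    gene = gene, level = level,
    sample_id = c(sprintf("BPH_%d", seq_along(bph)),
                  sprintf("PCa_%d", seq_along(pca))),
    group = rep(c("BPH", "PCa"), c(length(bph), length(pca))),
    log2_ratio = c(bph, pca),
    n_peptides = 1L
  )
}

## Comparison rows with just the columns the pattern classifier consumes.
make_comparison <- function(gene, level, p, eligible = TRUE, delta = NA_real_) {
  tibble::tibble(gene = gene, level = level, p_value = p,
                 eligible = eligible, delta = delta)
}
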