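#' Welch unequal-variance t statistic
#'
#' `t = (mean(x) - mean(y)) / sqrt(var(x)/nx + var(y)/ny)` with unbiased
#' sample variances. When both variances are zero the statistic is defined
#' as 0 for equal means and a signed infinity otherwise; the permutation
#' layer handles the sentinel.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return The t statistic (possibly `Inf`/`-Inf`).
#' @examples
#' welch_t(c(1, 2, 3), c(4, 5, 6))  # -3 / sqrt(2/3)
#' @export
welch_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) {
    abort("Both samples need at least two observations.",
          class = "mlacdiff_stat_error")
  }
  num <- mean(x) - mean(y)
  den <- sqrt(var(x) / nx + var(y) / ny)
  if (den == 0) {
    if (num == 0) 0 else sign(num) * Inf
  } else {
    num / den
  }
}

## Cache of combination index matrices keyed by "n,k": enumeration of the
## same cohort layout is reused across features and replicates.
.comb_cache <- new.env(parent = emptyenv())

comb_indices <- function(n, k) {
  key <- paste(n, k, sep = ",")
  if (is.null(.comb_cache[[key]])) .comb_cache[[key]] <- combn(n, k)
  .comb_cache[[key]]
}

## Vectorized Welch |t| for every column of an index matrix assigning
## `nx` of the pooled values to group x.
abs_t_for_assignments <- function(z, nx, idx) {
  n <- length(z); ny <- n - nx
  zm <- matrix(z[idx], nrow = nx)
  s1 <- colSums(zm); q1 <- colSums(zm * zm)
  tot <- sum(z); tot2 <- sum(z * z)
  m1 <- s1 / nx
  m2 <- (tot - s1) / ny
  v1 <- pmax((q1 - nx * m1^2) / (nx - 1), 0)
  v2 <- pmax((tot2 - q1 - ny * m2^2) / (ny - 1), 0)
  num <- m1 - m2
  den <- sqrt(v1 / nx + v2 / ny)
  tt <- ifelse(den > 0, num / den, ifelse(num == 0, 0, sign(num) * Inf))
  abs(tt)
}

## Tie-tolerant threshold: counts null statistics >= |t| up to a relative
## floating-point slack, so algebraically tied relabelings are included.
perm_threshold <- function(t_abs) {
  if (is.infinite(t_abs)) t_abs else t_abs - 1e-8 * (1 + t_abs)
}

## Core permutation engine. Enumerates all C(n, nx) group relabelings when
## that count is within `cap` (exact test; the observed labeling is one of
## them), otherwise draws `n_perm` random relabelings and applies the
## +1/+1 correction. Also returns plug-in p-values for `fdr_perms` sampled
## relabelings, scored against the same null distribution, for permutation
## FDR estimation.
perm_welch_full <- function(x, y, n_perm = 10000, cap = 100000, fdr_perms = 0) {
  z <- c(x, y)
  nx <- length(x)
  n <- length(z)
  t_obs <- welch_t(x, y)
  K <- choose(n, nx)
  exhaustive <- K <= cap
  if (exhaustive) {
    null_abs <- abs_t_for_assignments(z, nx, comb_indices(n, nx))
    p <- mean(null_abs >= perm_threshold(abs(t_obs)))
  } else {
    idx <- vapply(seq_len(n_perm), function(i) sample.int(n, nx), integer(nx))
    null_abs <- abs_t_for_assignments(z, nx, idx)
    p <- (sum(null_abs >= perm_threshold(abs(t_obs))) + 1) / (n_perm + 1)
  }
  perm_p <- numeric(0)
  if (fdr_perms > 0) {
    draws <- null_abs[sample.int(length(null_abs), fdr_perms, replace = TRUE)]
    perm_p <- vapply(draws,
                     function(v) mean(null_abs >= perm_threshold(v)),
                     numeric(1))
  }
  list(t_obs = t_obs, p = p, exhaustive = exhaustive,
       n_assignments = length(null_abs), perm_p = perm_p)
}

#' Two-sided permutation p-value for the Welch t statistic
#'
#' Relabels group membership of the pooled observations and compares the
#' absolute Welch statistic of each relabeling with the observed one. When
#' the number of distinct relabelings `C(nx+ny, nx)` is at most `cap`
#' (default 100,000 -- note `C(17, 7) = 19,448`, so a 7-vs-10 cohort is
#' enumerated exhaustively), the test is exact:
#' `p = #\{|t_perm| >= |t_obs|\} / C(nx+ny, nx)`. Otherwise `n_perm` random
#' relabelings are drawn and `p = (#\{|t_perm| >= |t_obs|\} + 1) / (n_perm + 1)`,
#' which never returns zero.
#'
#' @inheritParams welch_t
#' @param n_perm Number of Monte Carlo relabelings when enumeration is not
#'   feasible.
#' @param cap Maximum number of relabelings enumerated exhaustively.
#' @param seed Optional seed for the Monte Carlo path; `NULL` uses the
#'   current RNG state (exhaustive enumeration consumes no randomness).
#' @return The two-sided p-value.
#' @examples
#' permutation_pvalue(c(1, 2, 3), c(10, 11, 12))  # 2/20 = 0.1 exhaustively
#' @export
permutation_pvalue <- function(x, y, n_perm = 10000, cap = 100000, seed = NULL) {
  run <- function() perm_welch_full(x, y, n_perm = n_perm, cap = cap)$p
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Eligibility of features for the permutation test
#'
#' A (gene, level) feature is tested only when it was quantified in at
#' least `min_n` samples in both the BPH and the PCa group. Ineligible
#' features keep their group means (when computable) but receive no
#' p-value; features absent from a group in a fraction stay blank there.
#'
#' @param quant Normalized long quantification tibble
#'   (see [normalize_quant()]).
#' @param min_n Minimum per-group sample count (default 3).
#' @return Tibble: `gene`, `level`, `n_bph`, `n_pca`, `eligible`.
#' @export
eligibility_filter <- function(quant, min_n = 3) {
  quant %>%
    dplyr::group_by(.data$gene, .data$level) %>%
    dplyr::summarise(n_bph = sum(.data$group == "BPH"),
                     n_pca = sum(.data$group == "PCa"),
                     .groups = "drop") %>%
    dplyr::mutate(eligible = .data$n_bph >= min_n & .data$n_pca >= min_n)
}

#' Permutation-based false discovery rate
#'
#' Estimates, at each observed p-value threshold `t`, the FDR as the mean
#' number of permutation-null p-values at or below `t` divided by the
#' number of observed p-values at or below `t`, clipped to `[0, 1]` and
#' monotonized (non-decreasing in `t`, enforced by a running minimum from
#' the largest p downward). Permuted p-values must come from the same
#' relabeling scheme as the observed tests.
#'
#' @param observed_p Vector of observed p-values.
#' @param permuted_p Matrix (features x permutations) of null p-values, or
#'   anything coercible to one.
#' @return Tibble aligned with `observed_p`: columns `p`, `fdr_raw`
#'   (unmonotonized) and `fdr`.
#' @export
permutation_fdr <- function(observed_p, permuted_p) {
  m <- length(observed_p)
  if (m == 0L) {
    return(tibble(p = numeric(), fdr_raw = numeric(), fdr = numeric()))
  }
  pm <- as.matrix(permuted_p)
  if (nrow(pm) != m) {
    abort("`permuted_p` must have one row per observed p-value.",
          class = "mlacdiff_stat_error")
  }
  B <- ncol(pm)
  ord <- order(observed_p)
  ps <- observed_p[ord]
  n_obs_le <- findInterval(ps, ps)                       # #{observed <= t}
  n_perm_le <- findInterval(ps, sort(as.vector(pm))) / B # mean over perms
  fdr_raw <- pmin(1, n_perm_le / pmax(1, n_obs_le))
  fdr_mono <- rev(cummin(rev(fdr_raw)))
  out <- tibble(p = observed_p,
                fdr_raw = NA_real_, fdr = NA_real_)
  out$fdr_raw[ord] <- fdr_raw
  out$fdr[ord] <- fdr_mono
  out
}
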