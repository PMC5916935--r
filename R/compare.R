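#' Permutation Welch comparison of PCa vs BPH per gene and level
#'
#' For every (gene, level) feature of the normalized quantification matrix,
#' computes group means, their difference `delta = mean_pca - mean_bph`,
#' a two-sided permutation Welch t-test (exhaustive over all group
#' relabelings of the samples actually observed for that feature whenever
#' the enumeration fits within `perm_cap`, Monte Carlo otherwise) and a
#' permutation-based FDR. Features quantified in fewer than `min_n` samples
#' in either group keep their means but receive no p-value or FDR.
#'
#' Additional flags: `fc_flag` marks features whose PCa group mean log2 H/L
#' has absolute value at least `fc_log2` (the 1.5-fold-change inclusion
#' gate, `log2(1.5) = 0.585`); `significant` marks eligible features with
#' `p <= alpha`; `de_pass` marks those also under the FDR bound.
#'
#' @param quant Normalized long quantification tibble
#'   (see [normalize_quant()] / [quantify_evidence()]).
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @param fdr_bound FDR bound for the `de_pass` flag (default 0.01).
#' @param fc_log2 Fold-change gate on the absolute PCa group mean, log2
#'   scale (default `log2(1.5)`).
#' @param min_n Per-group eligibility minimum (default 3).
#' @param n_perm Monte Carlo relabelings when enumeration exceeds `perm_cap`.
#' @param perm_cap Maximum relabelings enumerated exhaustively.
#' @param fdr_perms Null relabelings sampled per feature for FDR estimation.
#' @param fdr_scope Compute the FDR separately per level (default) or
#'   pooled across all levels.
#' @param seed Integer seed governing all randomness (per-feature Monte
#'   Carlo streams are derived from it deterministically, so results do not
#'   depend on feature order).
#' @return An object of class `glyco_de`; use [tidy()] for the per-feature
#'   table, [glance()] for a one-row summary, [autoplot()] for the
#'   delta-by-fraction figure and [classify_patterns()] for the
#'   cross-fraction pattern groups.
#' @examples
#' cohort <- generate_cohort(cohort_design(n_proteins = 8, seed = 2))
#' fit <- compare_groups(quantify_evidence(cohort$evidence), seed = 2)
#' tidy(fit)
#' @export
compare_groups <- function(quant, alpha = 0.05, fdr_bound = 0.01,
                           fc_log2 = log2(1.5), min_n = 3,
                           n_perm = 10000, perm_cap = 100000,
                           fdr_perms = 100,
                           fdr_scope = c("level", "pooled"), seed = 1L) {
  fdr_scope <- match.arg(fdr_scope)
  stopifnot(alpha > 0, alpha < 1, fdr_bound > 0, fdr_bound < 1, fc_log2 >= 0)

  lev <- unique(as.character(quant$level))
  fractions <- c(intersect(MLAC_FRACTIONS, lev),
                 sort(setdiff(lev, c(MLAC_FRACTIONS, "GLOBAL"))))
  feats <- quant %>%
    dplyr::mutate(level = level_factor(.data$level, fractions)) %>%
    dplyr::group_by(.data$gene, .data$level) %>%
    dplyr::summarise(
      # sorted so every downstream draw depends only on the value multisets,
      # never on the row order of the input
      x = list(sort(.data$log2_ratio[.data$group == "PCa"])),
      y = list(sort(.data$log2_ratio[.data$group == "BPH"])),
      .groups = "drop"
    ) %>%
    dplyr::arrange(.data$gene, .data$level)

  feats <- feats %>%
    dplyr::mutate(
      n_pca = lengths(.data$x),
      n_bph = lengths(.data$y),
      mean_pca = vapply(.data$x, function(v) if (length(v)) mean(v) else NA_real_, numeric(1)),
      mean_bph = vapply(.data$y, function(v) if (length(v)) mean(v) else NA_real_, numeric(1)),
      delta = .data$mean_pca - .data$mean_bph,
      eligible = .data$n_bph >= min_n & .data$n_pca >= min_n
    )

  ## Deterministic per-feature RNG streams (feature order is canonical).
  feature_seeds <- withr::with_seed(seed,
    sample.int(.Machine$integer.max - 1L, nrow(feats)))

  res <- purrr::map(seq_len(nrow(feats)), function(i) {
    if (!feats$eligible[i]) {
      return(list(t = NA_real_, p = NA_real_, p_welch = NA_real_,
                  exhaustive = NA, perm_p = NULL))
    }
    x <- feats$x[[i]]; y <- feats$y[[i]]
    full <- withr::with_seed(feature_seeds[i],
      perm_welch_full(x, y, n_perm = n_perm, cap = perm_cap,
                      fdr_perms = fdr_perms))
    p_welch <- tryCatch(t.test(x, y)$p.value, error = function(e) NA_real_)
    list(t = full$t_obs, p = full$p, p_welch = p_welch,
         exhaustive = full$exhaustive, perm_p = full$perm_p)
  })

  comparisons <- feats %>%
    dplyr::select(-"x", -"y") %>%
    dplyr::mutate(
      t_stat = vapply(res, `[[`, numeric(1), "t"),
      p_value = vapply(res, `[[`, numeric(1), "p"),
      p_welch = vapply(res, `[[`, numeric(1), "p_welch"),
      exhaustive = vapply(res, function(r) isTRUE(r$exhaustive), logical(1)),
      fdr_raw = NA_real_, fdr = NA_real_
    )

  ## Permutation FDR, per level or pooled across levels.
  perm_mats <- res
  elig_idx <- which(comparisons$eligible)
  if (length(elig_idx) > 0L && fdr_perms > 0L) {
    groups <- if (fdr_scope == "level") {
      split(elig_idx, droplevels(comparisons$level[elig_idx]))
    } else {
      list(all = elig_idx)
    }
    for (idx in groups) {
      if (length(idx) == 0L) next
      pm <- do.call(rbind, lapply(perm_mats[idx], `[[`, "perm_p"))
      fd <- permutation_fdr(comparisons$p_value[idx], pm)
      comparisons$fdr_raw[idx] <- fd$fdr_raw
      comparisons$fdr[idx] <- fd$fdr
    }
  }

  comparisons <- comparisons %>%
    dplyr::mutate(
      fc_flag = !is.na(.data$mean_pca) & abs(.data$mean_pca) >= fc_log2,
      significant = .data$eligible & !is.na(.data$p_value) & .data$p_value <= alpha,
      de_pass = .data$eligible & !is.na(.data$fdr) & .data$fdr <= fdr_bound
    ) %>%
    dplyr::relocate("gene", "level", "n_bph", "n_pca", "mean_bph", "mean_pca",
                    "delta", "t_stat", "p_value", "fdr_raw", "fdr", "p_welch",
                    "eligible", "fc_flag", "significant", "de_pass")

  structure(
    list(
      comparisons = comparisons,
      params = list(alpha = alpha, fdr_bound = fdr_bound, fc_log2 = fc_log2,
                    min_n = min_n, n_perm = n_perm, perm_cap = perm_cap,
                    fdr_perms = fdr_perms, fdr_scope = fdr_scope, seed = seed),
      quant = quant
    ),
    class = "glyco_de"
  )
}

as_comparisons <- function(x) {
  if (inherits(x, "glyco_de")) x$comparisons else as_tibble(x)
}

#' @export
print.glyco_de <- function(x, ...) {
  cmp <- x$comparisons
  cat("<glyco_de>  permutation Welch comparison, PCa vs BPH\n")
  cat(sprintf("  features: %d tested / %d total; alpha = %g, FDR bound = %g\n",
              sum(cmp$eligible), nrow(cmp), x$params$alpha, x$params$fdr_bound))
  tab <- cmp %>%
    dplyr::filter(.data$eligible) %>%
    dplyr::group_by(.data$level) %>%
    dplyr::summarise(tested = dplyr::n(),
                     significant = sum(.data$significant), .groups = "drop")
  print(as.data.frame(tab), row.names = FALSE)
  invisible(x)
}

#' Tidy the per-feature comparison table of a `glyco_de` fit
#'
#' @param x A [compare_groups()] result.
#' @param ... Unused.
#' @return A tibble with one row per (gene, level) feature.
#' @export
tidy.glyco_de <- function(x, ...) {
  x$comparisons
}

#' One-row summary of a `glyco_de` fit
#'
#' @inheritParams tidy.glyco_de
#' @return A one-row tibble: features, eligible features, counts of
#'   significant features (overall and at the global level), FDR passes,
#'   and fold-change-gated significant features.
#' @export
glance.glyco_de <- function(x, ...) {
  cmp <- x$comparisons
  tibble(
    n_features = nrow(cmp),
    n_eligible = sum(cmp$eligible),
    n_significant = sum(cmp$significant),
    n_significant_global = sum(cmp$significant & cmp$level == "GLOBAL"),
    n_de_pass = sum(cmp$de_pass),
    n_fc_significant = sum(cmp$significant & cmp$fc_flag),
    alpha = x$params$alpha,
    fdr_bound = x$params$fdr_bound
  )
}
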