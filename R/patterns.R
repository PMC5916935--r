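#' Classify each gene's cross-fraction significance pattern
#'
#' Assigns every gene with at least one eligible comparison to one of the
#' pattern groups A-F (or `NONE`), describing how its differential
#' expression distributes across the lectin fractions and the global
#' protein level:
#' \describe{
#'   \item{A}{quantitated in all three fractions and significantly
#'     different in all three.}
#'   \item{B}{significantly different in every fraction it was quantitated
#'     in (but not quantitated in all three).}
#'   \item{D}{significantly different in multiple (>= 2) fractions without
#'     satisfying A or B.}
#'   \item{E}{significantly different in exactly one fraction and at the
#'     global level.}
#'   \item{F}{significantly different in exactly one fraction and not at
#'     the global level.}
#'   \item{C}{significant only at the global protein level.}
#' }
#' Rules are applied first-match in the precedence order A, B, D, E, F, C,
#' `NONE`, so a gene significant in all three fractions is A even though it
#' also matches D; A is decided by the fractions alone, so an all-fraction
#' gene whose opposing trends cancel at the global level is still A (these
#' are flagged by `sig_global = FALSE` in the output). Significance is
#' `p <= alpha` among eligible comparisons; a level with no eligible
#' comparison counts as not significant.
#'
#' @param x A [compare_groups()] fit or its tidied comparison tibble.
#' @param alpha Significance level (default 0.05).
#' @return Tibble: `gene`, `group_label` (factor A-F, NONE),
#'   `quantitated_fractions`, `significant_levels` (comma-separated),
#'   `n_sig_fractions`, `sig_global`.
#' @export
classify_patterns <- function(x, alpha = 0.05) {
  cmp <- as_comparisons(x)
  cmp %>%
    dplyr::mutate(level = as.character(.data$level)) %>%
    dplyr::group_by(.data$gene) %>%
    dplyr::group_modify(function(df, key) {
      elig <- df[df$eligible, , drop = FALSE]
      quant_fracs <- intersect(MLAC_FRACTIONS, elig$level)
      sig <- elig$level[!is.na(elig$p_value) & elig$p_value <= alpha]
      sig_fracs <- intersect(MLAC_FRACTIONS, sig)
      sig_global <- "GLOBAL" %in% sig
      tibble(
        group_label = classify_one(sig_fracs, quant_fracs, sig_global),
        quantitated_fractions = paste(quant_fracs, collapse = ","),
        significant_levels = paste(intersect(c(MLAC_FRACTIONS, "GLOBAL"), sig),
                                   collapse = ","),
        n_sig_fractions = length(sig_fracs),
        sig_global = sig_global
      )
    }) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(group_label = factor(.data$group_label,
                                       levels = c(LETTERS[1:6], "NONE")))
}

classify_one <- function(sig_fracs, quant_fracs, sig_global) {
  n_quant <- length(quant_fracs)
  n_sig <- length(sig_fracs)
  if (n_quant == 3L && n_sig == 3L) return("A")
  if (n_quant >= 1L && n_sig >= 1L && n_sig == n_quant) return("B")
  if (n_sig >= 2L) return("D")
  if (n_sig == 1L && sig_global) return("E")
  if (n_sig == 1L && !sig_global) return("F")
  if (n_sig == 0L && sig_global) return("C")
  "NONE"
}

#' Per-gene, per-level group-mean differences for plotting
#'
#' Emits the difference in mean log2 H/L between the groups
#' (`delta = mean PCa - mean BPH`) for every eligible comparison, with the
#' significance flag (`p <= alpha`, the asterisk convention) and the
#' gene's pattern group, ordered by pattern group then gene then level.
#'
#' @inheritParams classify_patterns
#' @return Tibble: `gene`, `group_label`, `level`, `delta`, `p_value`,
#'   `significant`.
#' @export
delta_table <- function(x, alpha = 0.05) {
  cmp <- as_comparisons(x)
  patterns <- classify_patterns(cmp, alpha = alpha)
  cmp %>%
    dplyr::filter(.data$eligible) %>%
    dplyr::left_join(dplyr::select(patterns, "gene", "group_label"), by = "gene") %>%
    dplyr::mutate(significant = !is.na(.data$p_value) & .data$p_value <= alpha) %>%
    dplyr::select("gene", "group_label", "level", "delta", "p_value",
                  "significant") %>%
    dplyr::arrange(.data$group_label, .data$gene, .data$level)
}

#' Group-mean heat-map matrix ordered by PCa global fold change
#'
#' Builds the gene x (fraction + global) matrix of group-mean log2 H/L
#' values underlying the expression heat map. Genes are included when
#' quantified in at least `min_n` samples of both groups at the global
#' level, and ordered from the largest PCa global mean downward. A cell is
#' blank (`NA`) when the group had fewer than `min_n` values there --
#' either too few data points or a glycoform never detected in that
#' fraction.
#'
#' @param quant Normalized long quantification tibble.
#' @param min_n Minimum per-(group, cell) sample count (default 3).
#' @return Wide tibble: `gene`, then one `<group>_<level>` column per
#'   group/level combination (e.g. `PCa_AAL`, `BPH_GLOBAL`).
#' @export
heatmap_matrix <- function(quant, min_n = 3) {
  cells <- quant %>%
    dplyr::group_by(.data$gene, .data$level, .data$group) %>%
    dplyr::summarise(mean_log2 = mean(.data$log2_ratio),
                     n = dplyr::n(), .groups = "drop") %>%
    dplyr::mutate(mean_log2 = ifelse(.data$n >= min_n, .data$mean_log2, NA_real_))

  keep <- cells %>%
    dplyr::filter(.data$level == "GLOBAL", !is.na(.data$mean_log2)) %>%
    dplyr::count(.data$gene) %>%
    dplyr::filter(.data$n == 2L) %>%  # both groups pass at the global level
    dplyr::pull(.data$gene)

  ord <- cells %>%
    dplyr::filter(.data$gene %in% keep, .data$group == "PCa",
                  .data$level == "GLOBAL") %>%
    dplyr::arrange(dplyr::desc(.data$mean_log2)) %>%
    dplyr::pull(.data$gene)

  cells %>%
    dplyr::filter(.data$gene %in% keep) %>%
    dplyr::mutate(cell = paste(.data$group, .data$level, sep = "_")) %>%
    dplyr::select("gene", "cell", "mean_log2") %>%
    tidyr::pivot_wider(names_from = "cell", values_from = "mean_log2") %>%
    dplyr::arrange(match(.data$gene, ord))
}

#' Plot group-mean differences by fraction and pattern group
#'
#' The summary figure of the analysis: per-gene differences in mean log2
#' H/L (PCa minus BPH) per lectin fraction and at the global level,
#' faceted by pattern group, significant comparisons (p <= alpha) marked
#' with an asterisk.
#'
#' @inheritParams classify_patterns
#' @return A ggplot object.
#' @export
plot_delta <- function(x, alpha = 0.05) {
  dt <- delta_table(x, alpha = alpha) %>%
    dplyr::filter(.data$group_label != "NONE")
  ggplot2::ggplot(dt, ggplot2::aes(x = .data$gene, y = .data$delta,
                                   fill = .data$level)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_text(
      data = dplyr::filter(dt, .data$significant),
      ggplot2::aes(label = "*", group = .data$level),
      position = ggplot2::position_dodge(width = 0.8), vjust = 0.2, size = 5
    ) +
    ggplot2::facet_grid(. ~ group_label, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = expression(Delta ~ "mean" ~ log[2] ~ "H/L (PCa - BPH)"),
                  fill = "Level") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       hjust = 1))
}

#' @rdname plot_delta
#' @param object A `glyco_de` fit.
#' @param ... Passed on (unused).
#' @export
autoplot.glyco_de <- function(object, alpha = object$params$alpha, ...) {
  plot_delta(object, alpha = alpha)
}

#' Plot the expression heat map
#'
#' Tile plot of group-mean log2 H/L per gene, lectin fraction and global
#' level, genes ordered by PCa global fold change; blank tiles are cells
#' with too few observations.
#'
#' @param hm Output of [heatmap_matrix()].
#' @return A ggplot object.
#' @export
plot_heatmap <- function(hm) {
  long <- hm %>%
    tidyr::pivot_longer(-"gene", names_to = "cell", values_to = "mean_log2") %>%
    tidyr::separate_wider_delim("cell", "_", names = c("group", "level")) %>%
    dplyr::mutate(level = level_factor(.data$level),
                  gene = factor(.data$gene, levels = rev(hm$gene)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$level, y = .data$gene,
                                     fill = .data$mean_log2)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(. ~ group) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  na.value = "grey95") +
    ggplot2::labs(x = NULL, y = NULL, fill = expression("mean" ~ log[2] ~ "H/L")) +
    ggplot2::theme_minimal()
}
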