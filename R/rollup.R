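#' Retain peptide evidence passing identification-confidence thresholds
#'
#' Keeps rows whose protein-group probability is strictly greater than
#' `protein_min` and whose peptide probability is strictly greater than
#' `peptide_min` (defaults 0.9 and 0.6) -- the retention rule applied to
#' search-engine validation scores before quantitation.
#'
#' @param evidence Peptide-evidence tibble with `protein_prob` and
#'   `peptide_prob` columns in `[0, 1]`.
#' @param protein_min,peptide_min Strict lower thresholds.
#' @return The retained rows, same columns.
#' @examples
#' ev <- tibble::tibble(protein_prob = c(0.95, 0.9), peptide_prob = c(0.7, 0.99))
#' confidence_filter(ev)  # keeps only the first row
#' @export
confidence_filter <- function(evidence, protein_min = 0.9, peptide_min = 0.6) {
  check_prob <- function(p, what) {
    if (any(p < 0 | p > 1, na.rm = TRUE)) {
      abort(paste0("`", what, "` must lie in [0, 1]."),
            class = "mlacdiff_schema_error")
    }
  }
  check_prob(evidence$protein_prob, "protein_prob")
  check_prob(evidence$peptide_prob, "peptide_prob")
  evidence %>%
    dplyr::filter(.data$protein_prob > protein_min,
                  .data$peptide_prob > peptide_min)
}

#' Assemble protein groups into gene groups with one representative name
#'
#' Rows whose `gene` annotation shares any gene name (multiple names may be
#' separated by `;` or `,`) are merged into one gene group, and the
#' lexicographically smallest member name (C-locale radix order, so the
#' choice is platform independent) is written back as the representative
#' `gene` on every row. The original annotation is preserved in
#' `gene_names`. Rows with an empty annotation are routed to the
#' `"unassigned"` group.
#'
#' @param evidence Peptide-evidence tibble with a `gene` column.
#' @return The same rows with `gene` replaced by the representative and a
#'   `gene_names` column holding the original annotation.
#' @examples
#' ev <- tibble::tibble(gene = c("C4B;C4A", "C4A", "AZGP1"))
#' assemble_gene_groups(ev)$gene  # "C4A" "C4A" "AZGP1"
#' @export
assemble_gene_groups <- function(evidence) {
  raw <- as.character(evidence$gene)
  name_lists <- strsplit(trimws(raw), "\\s*[;,]\\s*")
  name_lists <- lapply(name_lists, function(x) x[nzchar(x)])
  empty <- lengths(name_lists) == 0L
  if (any(empty)) {
    warn(sprintf("%d evidence row(s) without a gene name routed to 'unassigned'.",
                 sum(empty)))
    name_lists[empty] <- list("unassigned")
  }

  all_names <- sort(unique(unlist(name_lists)), method = "radix")
  parent <- seq_along(all_names)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  for (nm in name_lists) {
    idx <- match(nm, all_names)
    if (length(idx) > 1L) for (k in idx[-1]) union_(idx[1], k)
  }
  root <- vapply(seq_along(all_names), find, integer(1))
  ## Representative of a component = lexicographically smallest member;
  ## all_names is sorted, so the smallest index in a component is smallest.
  comp_rep <- all_names[vapply(root, function(r) min(which(root == root[r])), integer(1))]
  rep_of <- stats::setNames(comp_rep, all_names)

  evidence %>%
    dplyr::mutate(
      gene_names = vapply(name_lists, paste, character(1), collapse = ";"),
      gene = unname(rep_of[vapply(name_lists, `[`, character(1), 1)])
    )
}

#' Roll peptide H/L ratios up to protein level per fraction and globally
#'
#' For each (gene, sample, fraction), the protein-level H/L ratio is the
#' arithmetic mean of the peptide H/L ratios quantified there (on the
#' linear ratio scale; the log2 transform happens afterwards in
#' [normalize_quant()]). The `GLOBAL` protein level pools all quantified
#' peptides of the gene across fractions and averages them -- not the mean
#' of the fraction means -- so fractions contributing more peptides weigh
#' more. The alternative mean-of-fraction-means reading is available via
#' `global = "mean_of_means"`.
#'
#' Absent combinations yield no row (never a zero); missingness is carried
#' as absence throughout.
#'
#' @param evidence Filtered, gene-assembled peptide-evidence tibble with
#'   `gene`, `fraction`, `sample_id`, `group`, `hl_ratio`.
#' @param global How to compute the global level: `"pooled"` (default) or
#'   `"mean_of_means"`.
#' @return Long tibble: `gene`, `level` (fractions + `"GLOBAL"`),
#'   `sample_id`, `group`, `hl_ratio`, `n_peptides`.
#' @examples
#' ev <- tibble::tibble(
#'   gene = "G1", sample_id = "s1", group = "PCa",
#'   fraction = c("UNB", "UNB", "AAL"), hl_ratio = c(1, 1, 4))
#' rollup_evidence(ev)  # UNB 1, AAL 4, GLOBAL 2 (pooled over 3 peptides)
#' @export
rollup_evidence <- function(evidence, global = c("pooled", "mean_of_means")) {
  global <- match.arg(global)
  if (any(evidence$hl_ratio <= 0, na.rm = TRUE) || anyNA(evidence$hl_ratio)) {
    abort("All `hl_ratio` values must be positive and non-missing.",
          class = "mlacdiff_schema_error")
  }
  per_fraction <- evidence %>%
    dplyr::group_by(.data$gene, level = .data$fraction, .data$sample_id, .data$group) %>%
    dplyr::summarise(hl_ratio = mean(.data$hl_ratio),
                     n_peptides = dplyr::n(), .groups = "drop")
  global_lvl <- if (global == "pooled") {
    evidence %>%
      dplyr::group_by(.data$gene, .data$sample_id, .data$group) %>%
      dplyr::summarise(hl_ratio = mean(.data$hl_ratio),
                       n_peptides = dplyr::n(), .groups = "drop")
  } else {
    per_fraction %>%
      dplyr::group_by(.data$gene, .data$sample_id, .data$group) %>%
      dplyr::summarise(hl_ratio = mean(.data$hl_ratio),
                       n_peptides = sum(.data$n_peptides), .groups = "drop")
  }
  fractions <- unique(as.character(evidence$fraction))
  fractions <- c(intersect(MLAC_FRACTIONS, fractions),
                 setdiff(fractions, MLAC_FRACTIONS))
  dplyr::bind_rows(per_fraction,
                   dplyr::mutate(global_lvl, level = "GLOBAL")) %>%
    dplyr::mutate(level = level_factor(.data$level, fractions)) %>%
    dplyr::arrange(.data$gene, .data$level, .data$sample_id)
}

#' Median-center log2 values per sample
#'
#' Subtracts from every log2 value of a sample the median of that sample's
#' fraction-level values (all lectin fractions pooled; `GLOBAL` entries are
#' shifted by the same per-sample offset but do not contribute to the
#' median). After centering, each sample's pooled fraction-level median is
#' exactly zero, and the operation is idempotent.
#'
#' @param quant Long tibble with `level`, `sample_id` and `log2_ratio`.
#' @return Same tibble with `log2_ratio` centered.
#' @export
median_center_log2 <- function(quant) {
  stopifnot(all(c("level", "sample_id", "log2_ratio") %in% names(quant)))
  offsets <- quant %>%
    dplyr::filter(.data$level != "GLOBAL") %>%
    dplyr::group_by(.data$sample_id) %>%
    dplyr::summarise(offset = median(.data$log2_ratio), .groups = "drop")
  quant %>%
    dplyr::left_join(offsets, by = "sample_id") %>%
    dplyr::mutate(offset = dplyr::coalesce(.data$offset, 0),
                  log2_ratio = .data$log2_ratio - .data$offset) %>%
    dplyr::select(-"offset")
}

#' Log2-transform and normalize a rolled-up quantification table
#'
#' Transforms the protein-level H/L ratios of [rollup_evidence()] to log2
#' and median-centers them per sample across all lectin fractions (see
#' [median_center_log2()]), yielding the normalized quantification matrix
#' in long form.
#'
#' @param rolled Output of [rollup_evidence()].
#' @return Long tibble: `gene`, `level`, `sample_id`, `group`,
#'   `log2_ratio`, `n_peptides`.
#' @examples
#' ev <- tibble::tibble(
#'   gene = c("G1", "G2", "G3"), sample_id = "s1", group = "PCa",
#'   fraction = "UNB", hl_ratio = c(1, 2, 4))
#' normalize_quant(rollup_evidence(ev))  # centered log2: -1, 0, 1
#' @export
normalize_quant <- function(rolled) {
  bad <- which(rolled$hl_ratio <= 0 | is.na(rolled$hl_ratio))
  if (length(bad) > 0L) {
    abort(sprintf(
      "Non-positive H/L ratio at row %d (gene %s, level %s, sample %s): log2 undefined.",
      bad[1], rolled$gene[bad[1]], as.character(rolled$level[bad[1]]),
      rolled$sample_id[bad[1]]),
      class = "mlacdiff_schema_error")
  }
  rolled %>%
    dplyr::mutate(log2_ratio = log2(.data$hl_ratio)) %>%
    dplyr::select(-"hl_ratio") %>%
    median_center_log2() %>%
    dplyr::relocate("gene", "level", "sample_id", "group", "log2_ratio")
}

#' Full evidence-to-quantification chain
#'
#' Convenience wrapper: confidence filter, gene-group assembly, rollup and
#' normalization in one call.
#'
#' @inheritParams confidence_filter
#' @inheritParams rollup_evidence
#' @return Normalized long quantification tibble (see [normalize_quant()]).
#' @export
quantify_evidence <- function(evidence, protein_min = 0.9, peptide_min = 0.6,
                              global = c("pooled", "mean_of_means")) {
  global <- match.arg(global)
  evidence %>%
    confidence_filter(protein_min, peptide_min) %>%
    assemble_gene_groups() %>%
    rollup_evidence(global = global) %>%
    normalize_quant()
}
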