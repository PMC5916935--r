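## Tab-separated readers/writers for the pipeline's tables. Headers are
## fixed and documented on the corresponding generator/consumer functions.

evidence_cols <- function() {
  readr::cols(
    sample_id = readr::col_character(),
    group = readr::col_character(),
    fraction = readr::col_character(),
    protein_group = readr::col_character(),
    gene = readr::col_character(),
    peptide = readr::col_character(),
    n_cys = readr::col_integer(),
    protein_prob = readr::col_double(),
    peptide_prob = readr::col_double(),
    hl_ratio = readr::col_double()
  )
}

#' Read and write peptide-evidence tables
#'
#' Peptide evidence is exchanged as tab-separated text with the fixed
#' header `sample_id, group, fraction, protein_group, gene, peptide,
#' n_cys, protein_prob, peptide_prob, hl_ratio`.
#'
#' @param path File path.
#' @param evidence Evidence tibble (see [generate_cohort()]).
#' @return `read_evidence()` returns the tibble; `write_evidence()` its
#'   input, invisibly.
#' @export
read_evidence <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Evidence file not found: ", path),
          class = "mlacdiff_missing_input")
  }
  ## schema is validated below; silence the column-name mismatch chatter
  ev <- withCallingHandlers(
    readr::read_tsv(path, col_types = evidence_cols()),
    vroom_mismatched_column_name = function(w) invokeRestart("muffleWarning")
  )
  required <- c("sample_id", "group", "fraction", "gene", "protein_prob",
                "peptide_prob", "hl_ratio")
  missing <- setdiff(required, names(ev))
  if (length(missing) > 0L) {
    abort(paste0("Evidence table lacks column(s): ",
                 paste(missing, collapse = ", ")),
          class = "mlacdiff_schema_error")
  }
  ev
}

#' @rdname read_evidence
#' @export
write_evidence <- function(evidence, path) {
  readr::write_tsv(evidence, path)
  invisible(evidence)
}

#' Read and write the normalized quantification matrix
#'
#' Long-format tab-separated text: `gene, level, sample_id, group,
#' log2_ratio, n_peptides`.
#'
#' @param path File path.
#' @param quant Quantification tibble (see [normalize_quant()]).
#' @export
read_quant <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Quantification file not found: ", path),
          class = "mlacdiff_missing_input")
  }
  readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(),
    level = readr::col_character(),
    sample_id = readr::col_character(),
    group = readr::col_character(),
    log2_ratio = readr::col_double(),
    n_peptides = readr::col_integer()
  )) %>%
    dplyr::mutate(level = level_factor(.data$level))
}

#' @rdname read_quant
#' @export
write_quant <- function(quant, path) {
  readr::write_tsv(quant, path)
  invisible(quant)
}

#' Read and write elution-pair tables
#'
#' Pairs travel as two tab-separated files: a long profile table
#' (`pair_id, rt, light, heavy`, one row per grid point) and a sidecar
#' metadata table (`pair_id, charge, n_cys, theoretical_mass,
#' observed_mass`, plus `true_ratio` when known). `read_elution_pairs()`
#' reassembles the nested tibble consumed by [quantify_pairs()].
#'
#' @param pairs Nested pair tibble (see [generate_elution_pairs()]).
#' @param profile_path,meta_path File paths for the two tables.
#' @export
write_elution_pairs <- function(pairs, profile_path, meta_path) {
  long <- pairs %>%
    dplyr::select("pair_id", "rt", "light", "heavy") %>%
    tidyr::unnest(c("rt", "light", "heavy"))
  readr::write_tsv(long, profile_path)
  meta <- dplyr::select(pairs, -dplyr::where(is.list))
  readr::write_tsv(meta, meta_path)
  invisible(pairs)
}

#' @rdname write_elution_pairs
#' @export
read_elution_pairs <- function(profile_path, meta_path) {
  long <- readr::read_tsv(profile_path, col_types = readr::cols(
    pair_id = readr::col_character(), rt = readr::col_double(),
    light = readr::col_double(), heavy = readr::col_double()))
  meta <- readr::read_tsv(meta_path, col_types = readr::cols(
    pair_id = readr::col_character(), .default = readr::col_double()))
  nested <- long %>%
    dplyr::group_by(.data$pair_id) %>%
    dplyr::summarise(rt = list(.data$rt), light = list(.data$light),
                     heavy = list(.data$heavy), .groups = "drop")
  dplyr::left_join(meta, nested, by = "pair_id")
}
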