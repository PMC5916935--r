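#' Configuration for an end-to-end pipeline run
#'
#' Bundles every tunable of the pipeline: the simulation design (for
#' simulate modes), input paths (for analyze mode), statistical settings
#' and the seed. `fc_log2` defaults to `log2(1.5)` (0.585), the 1.5-fold
#' inclusion gate; `fdr_bound` defaults to 0.01, the 1% FDR bound for
#' differential quantification; `alpha` defaults to 0.05.
#'
#' @param mode `"simulate"`, `"analyze"` or `"end_to_end"`.
#' @param design A [cohort_design()] (simulate / end_to_end modes).
#' @param evidence_path Input evidence TSV (analyze mode).
#' @param out_dir Output directory (created if needed).
#' @param n_perm,perm_cap,fdr_perms,fdr_scope See [compare_groups()].
#' @param alpha,fdr_bound,fc_log2,min_n See [compare_groups()].
#' @param rp_fractions Number of reversed-phase fractions collected per
#'   lectin fraction upstream of MS. This dimension affects proteome depth,
#'   not the statistical model; it is recorded in the run manifest only.
#' @param seed Integer seed for the analysis stage.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("end_to_end", "simulate", "analyze"),
                            design = cohort_design(),
                            evidence_path = NULL,
                            out_dir = tempfile("mlacdiff_run_"),
                            n_perm = 10000, perm_cap = 100000,
                            fdr_perms = 100,
                            fdr_scope = c("level", "pooled"),
                            alpha = 0.05, fdr_bound = 0.01,
                            fc_log2 = log2(1.5), min_n = 3,
                            rp_fractions = 13,
                            seed = 1L) {
  mode <- match.arg(mode)
  fdr_scope <- match.arg(fdr_scope)
  if (alpha <= 0 || alpha >= 1 || fdr_bound <= 0 || fdr_bound >= 1) {
    abort("`alpha` and `fdr_bound` must lie in (0, 1).",
          class = "mlacdiff_config_error")
  }
  if (fc_log2 < 0) {
    abort("`fc_log2` must be nonnegative.", class = "mlacdiff_config_error")
  }
  if (mode == "analyze" && is.null(evidence_path)) {
    abort("analyze mode needs `evidence_path`.", class = "mlacdiff_config_error")
  }
  structure(
    list(mode = mode, design = design, evidence_path = evidence_path,
         out_dir = out_dir, n_perm = n_perm, perm_cap = perm_cap,
         fdr_perms = fdr_perms, fdr_scope = fdr_scope, alpha = alpha,
         fdr_bound = fdr_bound, fc_log2 = fc_log2, min_n = min_n,
         rp_fractions = as.integer(rp_fractions), seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys correspond to [pipeline_config()] arguments; the `design`
#' key is a mapping passed to [cohort_design()], with `effects` as a list
#' of mappings passed to [effect_spec()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Config file not found: ", path),
          class = "mlacdiff_missing_input")
  }
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$design)) {
    d <- raw$design
    if (!is.null(d$effects)) {
      d$effects <- dplyr::bind_rows(lapply(d$effects, function(e) do.call(effect_spec, e)))
    }
    if (!is.null(d$frac_presence_probs)) {
      d$frac_presence_probs <- unlist(d$frac_presence_probs)
    }
    raw$design <- do.call(cohort_design, d)
  }
  do.call(pipeline_config, raw)
}

#' Run the analysis pipeline end to end
#'
#' Orchestrates simulate -> quantify -> roll up -> test -> classify ->
#' export with seeded reproducibility. Depending on `config$mode`:
#' `"simulate"` writes the evidence table and ground truth only;
#' `"analyze"` reads evidence from `config$evidence_path` and runs the
#' statistical stages; `"end_to_end"` does both. Identical config and seed
#' give byte-identical output tables.
#'
#' All exclusions are counted, never silent: the manifest records rows
#' dropped by the confidence filter and the per-feature eligibility rule,
#' together with the configuration, seed, package version and row counts
#' of every table written.
#'
#' @param config A [pipeline_config()] (or a YAML path accepted by
#'   [read_pipeline_config()]).
#' @return Invisibly, a list of class `glyco_run` with the in-memory
#'   objects (`cohort`, `quant`, `fit`, `patterns`, `deltas`, `heatmap`),
#'   the `manifest`, and `paths` of everything written.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(config$out_dir)) {
    abort(paste0("Cannot create output directory: ", config$out_dir),
          class = "mlacdiff_output_error")
  }
  paths <- list()
  manifest <- list(
    package = "mlacdiff",
    version = as.character(packageVersion("mlacdiff")),
    mode = config$mode,
    seed = config$seed,
    rp_fractions = config$rp_fractions,
    mlac_fractions = length(config$design$fractions),
    fraction_slots_per_sample = config$rp_fractions * length(config$design$fractions),
    params = list(alpha = config$alpha, fdr_bound = config$fdr_bound,
                  fc_log2 = config$fc_log2, min_n = config$min_n,
                  n_perm = config$n_perm, perm_cap = config$perm_cap,
                  fdr_scope = config$fdr_scope)
  )

  cohort <- NULL
  evidence <- NULL
  if (config$mode %in% c("simulate", "end_to_end")) {
    cohort <- generate_cohort(config$design)
    evidence <- cohort$evidence
    paths$evidence <- file.path(config$out_dir, "evidence.tsv")
    write_evidence(evidence, paths$evidence)
    paths$truth_effects <- file.path(config$out_dir, "truth_effects.tsv")
    readr::write_tsv(cohort$truth$effects, paths$truth_effects)
    paths$truth_latent <- file.path(config$out_dir, "truth_latent.tsv")
    readr::write_tsv(cohort$truth$latent, paths$truth_latent)
    manifest$design <- list(
      n_bph = config$design$n_bph, n_pca = config$design$n_pca,
      fractions = config$design$fractions,
      n_proteins = config$design$n_proteins,
      missing_rate = config$design$missing_rate,
      noise_sd = config$design$noise_sd,
      design_seed = config$design$seed,
      n_effects = nrow(config$design$effects)
    )
  }
  if (config$mode == "analyze") {
    evidence <- read_evidence(config$evidence_path)
    manifest$evidence_path <- config$evidence_path
  }
  manifest$n_evidence_rows <- if (is.null(evidence)) 0L else nrow(evidence)

  fit <- NULL; quant <- NULL; patterns <- NULL; deltas <- NULL; hm <- NULL
  if (config$mode %in% c("analyze", "end_to_end")) {
    filtered <- confidence_filter(evidence)
    manifest$exclusions <- list(
      confidence_filter = nrow(evidence) - nrow(filtered)
    )
    assembled <- assemble_gene_groups(filtered)
    quant <- normalize_quant(rollup_evidence(assembled))
    fit <- compare_groups(quant, alpha = config$alpha,
                          fdr_bound = config$fdr_bound,
                          fc_log2 = config$fc_log2, min_n = config$min_n,
                          n_perm = config$n_perm, perm_cap = config$perm_cap,
                          fdr_perms = config$fdr_perms,
                          fdr_scope = config$fdr_scope, seed = config$seed)
    cmp <- tidy(fit)
    manifest$exclusions$ineligible_features <- sum(!cmp$eligible)
    patterns <- classify_patterns(fit, alpha = config$alpha)
    deltas <- delta_table(fit, alpha = config$alpha)
    hm <- heatmap_matrix(quant, min_n = config$min_n)

    paths$quant <- file.path(config$out_dir, "quant_matrix.tsv")
    write_quant(quant, paths$quant)
    paths$comparisons <- file.path(config$out_dir, "comparisons.tsv")
    readr::write_tsv(cmp, paths$comparisons)
    paths$patterns <- file.path(config$out_dir, "patterns.tsv")
    readr::write_tsv(patterns, paths$patterns)
    paths$deltas <- file.path(config$out_dir, "delta_table.tsv")
    readr::write_tsv(deltas, paths$deltas)
    paths$heatmap <- file.path(config$out_dir, "heatmap_matrix.tsv")
    readr::write_tsv(hm, paths$heatmap)

    manifest$n_quant_rows <- nrow(quant)
    manifest$n_features <- nrow(cmp)
    manifest$n_eligible <- sum(cmp$eligible)
    manifest$n_significant <- sum(cmp$significant)
    manifest$n_heatmap_genes <- nrow(hm)
  }

  paths$manifest <- file.path(config$out_dir, "manifest.yml")
  yaml::write_yaml(manifest, paths$manifest)

  invisible(structure(
    list(cohort = cohort, quant = quant, fit = fit, patterns = patterns,
         deltas = deltas, heatmap = hm, manifest = manifest, paths = paths,
         config = config),
    class = "glyco_run"
  ))
}

#' @export
print.glyco_run <- function(x, ...) {
  cat("<glyco_run>  mode:", x$config$mode, "\n")
  cat("  out_dir:", x$config$out_dir, "\n")
  cat(sprintf("  fraction slots per sample: %d (%d RP x %d M-LAC)\n",
              x$manifest$fraction_slots_per_sample, x$manifest$rp_fractions,
              x$manifest$mlac_fractions))
  if (!is.null(x$fit)) print(x$fit)
  invisible(x)
}
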