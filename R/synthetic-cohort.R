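#' Generate a synthetic peptide-evidence cohort with known ground truth
#'
#' Simulates the peptide-level evidence table that the downstream pipeline
#' consumes, together with the latent truth used to generate it. One row of
#' evidence is one surviving (sample, peptide, fraction) observation with a
#' heavy/light ratio `2^(latent log2 + measurement noise)`. Only peptides
#' with at least one cysteine are emitted as quantifiable, because only
#' cysteines carry the acrylamide isotope label; zero-cysteine peptides are
#' drawn and then discarded, so the constraint is actually exercised.
#'
#' The reference pool is implicit: each heavy/light ratio already encodes
#' case-versus-reference, mirroring the paired labeling design, so no
#' separate reference rows are emitted.
#'
#' @param design A [cohort_design()].
#' @return An object of class `glyco_cohort`: a list with
#'   \describe{
#'     \item{evidence}{tibble of quantifiable peptide observations
#'       (`sample_id`, `group`, `fraction`, `protein_group`, `gene`,
#'       `peptide`, `n_cys`, `protein_prob`, `peptide_prob`, `hl_ratio`).}
#'     \item{truth}{list with `effects` (realized effect table) and `latent`
#'       (tibble of per-(gene, fraction, sample) latent log2 ratios); every
#'       evidence row joins to exactly one latent row.}
#'     \item{design}{the design used.}
#'   }
#' @examples
#' cohort <- generate_cohort(cohort_design(n_proteins = 10, seed = 7))
#' head(cohort$evidence)
#' @export
generate_cohort <- function(design) {
  validate_cohort_design(design)
  withr::with_seed(design$seed, gen_cohort_impl(design))
}

gen_cohort_impl <- function(design) {
  samples <- tibble(
    sample_id = c(sprintf("BPH_%d", seq_len(design$n_bph)),
                  sprintf("PCa_%d", seq_len(design$n_pca))),
    group = rep(c("BPH", "PCa"), c(design$n_bph, design$n_pca))
  )

  effects <- design$effects
  genes <- sprintf("GENE%04d", seq_len(design$n_proteins))
  extra <- setdiff(unique(effects$gene), genes)
  if (length(extra) > 0L) genes <- c(genes, extra)

  probs <- design$frac_presence_probs
  if (is.null(names(probs))) names(probs) <- design$fractions

  ## Fraction occupancy: Bernoulli per (gene, fraction); every gene is
  ## forced into at least one fraction, and fraction-scoped effects force
  ## occupancy of their fraction so the injected contrast is observable.
  occ <- tidyr::expand_grid(gene = genes, fraction = design$fractions)
  occ$present <- runif(nrow(occ)) < unname(probs[occ$fraction])
  none <- tapply(occ$present, occ$gene, sum)[genes] == 0
  if (any(none)) {
    forced <- sample(design$fractions, sum(none), replace = TRUE)
    idx <- match(paste(genes[none], forced), paste(occ$gene, occ$fraction))
    occ$present[idx] <- TRUE
  }
  frac_eff <- effects[effects$scope != "GLOBAL", , drop = FALSE]
  if (nrow(frac_eff) > 0L) {
    idx <- match(paste(frac_eff$gene, frac_eff$scope), paste(occ$gene, occ$fraction))
    occ$present[idx] <- TRUE
  }

  ## Per-gene baseline vs the reference pool; effect genes use their stated
  ## baseline, others are drawn once.
  baselines <- tibble(gene = genes,
                      baseline_log2 = rnorm(length(genes), 0, design$baseline_sd))
  if (nrow(effects) > 0L) {
    eff_base <- effects %>%
      dplyr::distinct(.data$gene, .keep_all = TRUE) %>%
      dplyr::select("gene", "group_baseline_log2")
    hit <- match(eff_base$gene, baselines$gene)
    baselines$baseline_log2[hit] <- eff_base$group_baseline_log2
  }

  occ <- occ %>%
    dplyr::filter(.data$present) %>%
    dplyr::select("gene", "fraction") %>%
    dplyr::left_join(baselines, by = "gene")
  occ$delta_log2 <- vapply(seq_len(nrow(occ)), function(i) {
    hit <- effects$gene == occ$gene[i] &
      (effects$scope == "GLOBAL" | effects$scope == occ$fraction[i])
    sum(effects$delta_log2[hit])
  }, numeric(1))

  ## Peptide catalog per gene (fixed across samples/fractions).
  n_pep <- resample(design$peptides_per_protein, length(genes))
  peptides <- tibble(
    gene = rep(genes, n_pep),
    n_cys = resample(design$cys_per_peptide, sum(n_pep))
  )
  peptides$peptide <- make_peptides(peptides$n_cys)

  ## Latent log2 ratio per (gene, fraction, sample): baseline + group
  ## effect + biological noise.
  latent <- tidyr::crossing(occ, samples)
  latent$latent_log2 <- latent$baseline_log2 +
    latent$delta_log2 * (latent$group == "PCa") +
    rnorm(nrow(latent), 0, design$noise_sd)
  latent_out <- latent %>%
    dplyr::select("gene", "fraction", "sample_id", "group", "latent_log2") %>%
    dplyr::arrange(.data$gene, .data$fraction, .data$sample_id)

  ## Peptide observations: latent + measurement noise, then cysteine
  ## quantifiability and random dropout.
  obs <- latent %>%
    dplyr::select("gene", "fraction", "sample_id", "group", "latent_log2") %>%
    dplyr::inner_join(peptides, by = "gene", relationship = "many-to-many")
  obs$obs_log2 <- obs$latent_log2 + rnorm(nrow(obs), 0, design$noise_sd)
  quantifiable <- obs$n_cys >= 1L
  kept <- runif(nrow(obs)) >= design$missing_rate
  obs <- obs[quantifiable & kept, , drop = FALSE]

  n <- nrow(obs)
  low_p <- runif(n) < design$low_conf_rate
  low_q <- runif(n) < design$low_conf_rate
  protein_prob <- ifelse(low_p, runif(n, 0.4, 0.9), runif(n, 0.905, 1))
  peptide_prob <- ifelse(low_q, runif(n, 0.1, 0.6), runif(n, 0.62, 1))

  evidence <- tibble(
    sample_id = obs$sample_id,
    group = obs$group,
    fraction = obs$fraction,
    protein_group = paste0("ACC_", obs$gene),
    gene = obs$gene,
    peptide = obs$peptide,
    n_cys = obs$n_cys,
    protein_prob = protein_prob,
    peptide_prob = peptide_prob,
    hl_ratio = 2^obs$obs_log2
  ) %>%
    dplyr::arrange(.data$gene, .data$fraction, .data$sample_id, .data$peptide)

  structure(
    list(evidence = evidence,
         truth = list(effects = effects, latent = latent_out),
         design = design),
    class = "glyco_cohort"
  )
}

resample <- function(x, n) x[sample.int(length(x), n, replace = TRUE)]

## Tryptic-looking peptide strings with a prescribed number of cysteines.
make_peptides <- function(n_cys) {
  aa <- strsplit("ADEFGHILMNPQSTVWY", "")[[1]]
  vapply(n_cys, function(k) {
    len <- sample(7:14, 1L)
    body <- resample(aa, len)
    if (k > 0) body[sample.int(len, min(k, len))] <- "C"
    paste0(paste(body, collapse = ""), resample(c("K", "R"), 1L))
  }, character(1))
}

#' @export
print.glyco_cohort <- function(x, ...) {
  cat("<glyco_cohort>\n")
  cat(sprintf("  %d evidence rows, %d genes, %d samples\n",
              nrow(x$evidence), dplyr::n_distinct(x$evidence$gene),
              dplyr::n_distinct(x$evidence$sample_id)))
  cat(sprintf("  %d injected effect(s)\n", nrow(x$truth$effects)))
  invisible(x)
}

#' Generate isotope-pair elution profiles with known true ratios
#'
#' Emits paired light/heavy extracted elution profiles for labeled
#' peptides, each carrying the heavy/light ratio that generated it, for
#' testing the isotope-pair quantifier. Profiles are Gaussian-shaped over a
#' fixed retention grid; the heavy profile is the light profile scaled by
#' the true ratio with optional multiplicative point noise (mean-one
#' lognormal, so the integrated ratio stays unbiased). The heavy species
#' sits `3 * n_cys / charge` Th above the light species, the nominal 3 Da
#' per-cysteine label difference divided by charge.
#'
#' @param design A [cohort_design()]; supplies the seed and the cysteine
#'   count range (restricted to >= 1, since unlabeled peptides have no
#'   heavy partner).
#' @param n_pairs Number of pairs to generate.
#' @param profile_noise Standard deviation of lognormal point noise on the
#'   heavy profile (0 = exact scaling).
#' @param ppm_sd Standard deviation (ppm) of precursor mass error for
#'   well-measured pairs.
#' @param ppm_outlier_rate Fraction of pairs given a gross mass error
#'   (25-60 ppm) so the mass-accuracy filter is exercised.
#' @param rt_points Number of retention-time grid points.
#' @param true_ratio,n_cys,charge Optional overrides (recycled across
#'   pairs) replacing the randomly drawn values, for controlled tests.
#' @return A tibble with one row per pair: `pair_id`, `true_ratio`,
#'   `charge`, `n_cys`, `theoretical_mass`, `observed_mass`, `light_mz`,
#'   `heavy_mz`, and list-columns `rt`, `light`, `heavy`.
#' @examples
#' pairs <- generate_elution_pairs(cohort_design(seed = 3), n_pairs = 5)
#' pairs$true_ratio
#' @export
generate_elution_pairs <- function(design, n_pairs = 100,
                                   profile_noise = 0.02,
                                   ppm_sd = 3, ppm_outlier_rate = 0.05,
                                   rt_points = 41,
                                   true_ratio = NULL, n_cys = NULL,
                                   charge = NULL) {
  validate_cohort_design(design)
  stopifnot(n_pairs >= 1, rt_points >= 4, profile_noise >= 0)
  withr::with_seed(design$seed, {
    cys_pool <- design$cys_per_peptide[design$cys_per_peptide >= 1L]
    if (length(cys_pool) == 0L) cys_pool <- 1L
    proton <- 1.007276
    grid <- seq(0, 2, length.out = rt_points)

    out <- tibble(
      pair_id = sprintf("pair_%04d", seq_len(n_pairs)),
      true_ratio = if (is.null(true_ratio)) 2^rnorm(n_pairs, 0, 1)
                   else rep_len(true_ratio, n_pairs),
      charge = if (is.null(charge)) resample(2:3, n_pairs)
               else rep_len(as.integer(charge), n_pairs),
      n_cys = if (is.null(n_cys)) resample(cys_pool, n_pairs)
              else rep_len(as.integer(n_cys), n_pairs),
      theoretical_mass = runif(n_pairs, 800, 3500)
    )
    if (any(out$n_cys < 1L)) {
      abort("Elution pairs require n_cys >= 1 (no label site otherwise).",
            class = "mlacdiff_unquantifiable")
    }
    outlier <- runif(n_pairs) < ppm_outlier_rate
    ppm_err <- ifelse(outlier,
                      sample(c(-1, 1), n_pairs, replace = TRUE) * runif(n_pairs, 25, 60),
                      rnorm(n_pairs, 0, ppm_sd))
    out$observed_mass <- out$theoretical_mass * (1 + ppm_err * 1e-6)
    out$light_mz <- (out$theoretical_mass + out$charge * proton) / out$charge
    out$heavy_mz <- out$light_mz + 3 * out$n_cys / out$charge

    centers <- runif(n_pairs, 0.7, 1.3)
    widths <- runif(n_pairs, 0.10, 0.20)
    amps <- 2^runif(n_pairs, 8, 16)
    out$rt <- rep(list(grid), n_pairs)
    out$light <- purrr::pmap(list(centers, widths, amps),
                             function(c0, w, a) a * dnorm(grid, c0, w))
    out$heavy <- purrr::pmap(list(out$light, out$true_ratio), function(l, r) {
      noise <- if (profile_noise > 0) {
        exp(rnorm(length(l), -profile_noise^2 / 2, profile_noise))
      } else {
        1
      }
      r * l * noise
    })
    out
  })
}

#' Clinical characteristics of the PCa and BPH cohort
#'
#' Returns the packaged 17-row clinical-characteristics table: ten prostate
#' cancer patients (age, PSA, percent Gleason pattern 4/5, total cancer
#' volume in cc, all with pathological Gleason score 4+3=7) and seven
#' benign prostatic hyperplasia patients (cancer-specific fields `NA`).
#'
#' @return A tibble with columns `sample_id`, `sample_type`, `age`,
#'   `psa_ng_ml`, `percent_g4_5`, `total_cancer_volume_cc`, `gleason`.
#' @examples
#' clinical_fixture() %>% dplyr::count(sample_type)
#' @export
clinical_fixture <- function() {
  path <- system.file("extdata", "clinical_characteristics.tsv",
                      package = "mlacdiff", mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    sample_type = readr::col_character(),
    age = readr::col_double(),
    psa_ng_ml = readr::col_double(),
    percent_g4_5 = readr::col_double(),
    total_cancer_volume_cc = readr::col_double(),
    gleason = readr::col_character()
  ))
}
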