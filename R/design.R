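#' Specify an injected group effect for the synthetic cohort
#'
#' An effect is a true difference in mean log2 heavy/light ratio between the
#' PCa and BPH groups for one gene, applied either to every lectin fraction
#' the gene occupies (`scope = "GLOBAL"`) or to a single fraction
#' (`"UNB"`, `"AAL"` or `"PHA"`). Fraction-scoped effects are the
#' glycoform-specific alterations the lectin separation is designed to
#' expose; global effects move the whole protein.
#'
#' @param gene Gene symbol the effect applies to.
#' @param scope `"GLOBAL"` or one of the lectin-fraction labels.
#' @param delta_log2 True group-mean difference, PCa minus BPH, in log2
#'   heavy/light units.
#' @param group_baseline_log2 Shared log2 shift of both groups relative to
#'   the reference pool (the gene's baseline abundance change).
#' @return A one-row tibble with columns `gene`, `scope`, `delta_log2`,
#'   `group_baseline_log2`.
#' @examples
#' effect_spec("GENE0001", scope = "PHA", delta_log2 = 1.5)
#' @export
effect_spec <- function(gene, scope = "GLOBAL", delta_log2 = 0,
                        group_baseline_log2 = 0) {
  stopifnot(is.character(gene), length(gene) == 1L, nzchar(gene))
  scope <- as.character(scope)
  if (!is.numeric(delta_log2) || length(delta_log2) != 1L) {
    abort("`delta_log2` must be a single number.", class = "mlacdiff_design_error")
  }
  tibble(
    gene = gene, scope = scope,
    delta_log2 = as.numeric(delta_log2),
    group_baseline_log2 = as.numeric(group_baseline_log2)
  )
}

#' Describe a synthetic serum glycoproteomics cohort
#'
#' A cohort design captures the study layout the simulator reproduces: two
#' patient groups (benign prostatic hyperplasia and prostate cancer), each
#' sample quantified as heavy/light isotope ratios against a common
#' reference pool; proteins whose glycoforms partition across three
#' multi-lectin affinity fractions (UNB flow-through, AAL-bound
#' core-fucosylated, PHA-bound highly-branched); and quantification
#' restricted to cysteine-containing peptides, since only cysteines carry
#' the acrylamide isotope label. Defaults reproduce a 7 BPH / 10 PCa serum
#' comparison.
#'
#' The latent model is: each gene carries a baseline log2 ratio versus the
#' reference pool; for each occupied (gene, fraction), PCa samples are
#' additionally shifted by the summed applicable `delta_log2` effects; the
#' per-sample latent value adds Normal(0, `noise_sd`) biological noise, and
#' every quantified peptide observation adds independent Normal(0,
#' `noise_sd`) measurement noise on the log2 scale.
#'
#' @param n_bph,n_pca Number of BPH and PCa samples.
#' @param fractions Ordered lectin-fraction labels.
#' @param n_proteins Number of simulated proteins (gene groups); genes named
#'   in `effects` but not covered by this count are appended.
#' @param peptides_per_protein Integer vector of candidate peptide counts
#'   per protein; one value is drawn per protein.
#' @param cys_per_peptide Integer vector (values >= 0) of candidate cysteine
#'   counts per peptide. Peptides drawn with zero cysteines are generated
#'   but excluded from the quantifiable output, mimicking the
#'   cysteine-label-only quantification constraint.
#' @param frac_presence_probs Per-fraction probability that a protein's
#'   glycoform appears in that fraction; named by fraction or positional.
#' @param missing_rate Per-(sample, peptide, fraction) dropout probability.
#' @param noise_sd Standard deviation (log2 units) of both the sample-level
#'   biological noise and the peptide-level measurement noise.
#' @param baseline_sd Standard deviation of per-gene baseline log2 ratios
#'   versus the reference pool for genes without an explicit effect.
#' @param low_conf_rate Fraction of evidence rows drawn with identification
#'   probabilities below the retention thresholds, so the confidence filter
#'   has work to do.
#' @param effects List of [effect_spec()] rows (or a tibble of them).
#' @param seed Integer seed; all randomness in generation flows from it.
#' @return An object of class `cohort_design`.
#' @seealso [generate_cohort()], [generate_elution_pairs()]
#' @examples
#' design <- cohort_design(n_proteins = 20,
#'   effects = list(effect_spec("GENE0001", "PHA", delta_log2 = 1)))
#' @export
cohort_design <- function(n_bph = 7, n_pca = 10,
                          fractions = c("UNB", "AAL", "PHA"),
                          n_proteins = 120,
                          peptides_per_protein = 2:6,
                          cys_per_peptide = 0:3,
                          frac_presence_probs = c(UNB = 0.80, AAL = 0.55, PHA = 0.55),
                          missing_rate = 0.15,
                          noise_sd = 0.4,
                          baseline_sd = 0.5,
                          low_conf_rate = 0.05,
                          effects = list(),
                          seed = 1L) {
  design <- structure(
    list(
      n_bph = as.integer(n_bph), n_pca = as.integer(n_pca),
      fractions = as.character(fractions),
      n_proteins = as.integer(n_proteins),
      peptides_per_protein = as.integer(peptides_per_protein),
      cys_per_peptide = as.integer(cys_per_peptide),
      frac_presence_probs = frac_presence_probs,
      missing_rate = missing_rate,
      noise_sd = noise_sd,
      baseline_sd = baseline_sd,
      low_conf_rate = low_conf_rate,
      effects = normalize_effects(effects),
      seed = as.integer(seed)
    ),
    class = "cohort_design"
  )
  validate_cohort_design(design)
}

normalize_effects <- function(effects) {
  if (is.data.frame(effects)) {
    eff <- as_tibble(effects)
  } else if (is.list(effects)) {
    eff <- dplyr::bind_rows(effects)
  } else {
    abort("`effects` must be a list of effect_spec() rows or a data frame.",
          class = "mlacdiff_design_error")
  }
  if (nrow(eff) == 0L) {
    return(tibble(gene = character(), scope = character(),
                  delta_log2 = numeric(), group_baseline_log2 = numeric()))
  }
  needed <- c("gene", "scope", "delta_log2")
  if (!all(needed %in% names(eff))) {
    abort("Each effect needs `gene`, `scope` and `delta_log2`.",
          class = "mlacdiff_design_error")
  }
  if (!"group_baseline_log2" %in% names(eff)) eff$group_baseline_log2 <- 0
  eff
}

validate_cohort_design <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  if (design$n_bph < 0 || design$n_pca < 0) {
    abort("Sample counts must be nonnegative.", class = "mlacdiff_design_error")
  }
  if (length(design$fractions) == 0L) {
    abort("`fractions` must name at least one lectin fraction.",
          class = "mlacdiff_design_error")
  }
  if (design$n_proteins <= 0L) {
    abort("`n_proteins` must be positive.", class = "mlacdiff_design_error")
  }
  p <- design$frac_presence_probs
  if (length(p) != length(design$fractions)) {
    abort("`frac_presence_probs` must have one entry per fraction.",
          class = "mlacdiff_design_error")
  }
  if (is.null(names(p)) || !all(nzchar(names(p)))) {
    names(design$frac_presence_probs) <- design$fractions
    p <- design$frac_presence_probs
  }
  if (!setequal(names(p), design$fractions)) {
    abort("`frac_presence_probs` names must match `fractions`.",
          class = "mlacdiff_design_error")
  }
  if (any(p < 0 | p > 1)) {
    abort("`frac_presence_probs` entries must lie in [0, 1].",
          class = "mlacdiff_design_error")
  }
  if (design$missing_rate < 0 || design$missing_rate > 1) {
    abort("`missing_rate` must lie in [0, 1].", class = "mlacdiff_design_error")
  }
  if (design$noise_sd < 0 || design$baseline_sd < 0) {
    abort("Noise standard deviations must be nonnegative.",
          class = "mlacdiff_design_error")
  }
  if (any(design$cys_per_peptide < 0)) {
    abort("`cys_per_peptide` values must be >= 0.", class = "mlacdiff_design_error")
  }
  if (any(design$peptides_per_protein < 1)) {
    abort("`peptides_per_protein` values must be >= 1.",
          class = "mlacdiff_design_error")
  }
  bad_scope <- setdiff(unique(design$effects$scope), c("GLOBAL", design$fractions))
  if (length(bad_scope) > 0L) {
    abort(paste0("Unknown effect scope(s): ", paste(bad_scope, collapse = ", ")),
          class = "mlacdiff_design_error")
  }
  design
}

#' @export
print.cohort_design <- function(x, ...) {
  cat("<cohort_design>\n")
  cat(sprintf("  samples:   %d BPH + %d PCa\n", x$n_bph, x$n_pca))
  cat(sprintf("  fractions: %s\n", paste(x$fractions, collapse = ", ")))
  cat(sprintf("  proteins:  %d (%d injected effect%s)\n", x$n_proteins,
              nrow(x$effects), if (nrow(x$effects) == 1) "" else "s"))
  cat(sprintf("  noise_sd=%.3g  missing_rate=%.3g  seed=%d\n",
              x$noise_sd, x$missing_rate, x$seed))
  invisible(x)
}
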