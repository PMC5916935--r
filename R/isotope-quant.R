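#' Acrylamide label mass difference per cysteine
#'
#' Cases are alkylated with 1,2,3-13C3 (heavy) acrylamide and the reference
#' pool with 12C3 (light) acrylamide, so each labeled cysteine shifts the
#' peptide mass by nominally 3 Da. The exact 13C3-12C3 difference
#' (3 x 1.0033548 Da) is exposed for mass bookkeeping but the nominal value
#' is the default throughout.
#'
#' @format Numeric scalars, in daltons.
#' @export
ACRYLAMIDE_SHIFT_NOMINAL_DA <- 3

#' @rdname ACRYLAMIDE_SHIFT_NOMINAL_DA
#' @export
ACRYLAMIDE_SHIFT_EXACT_DA <- 3 * 1.0033548378

#' Expected heavy-light m/z shift for a labeled peptide
#'
#' The heavy form of a peptide with `n_cys` labeled cysteines sits
#' `label_shift_da * n_cys / charge` Th above its light form in the mass
#' spectrum.
#'
#' @param n_cys Number of cysteines (label sites); vectorized. A peptide
#'   with zero cysteines carries no label and is not quantifiable, so
#'   `n_cys = 0` is an error.
#' @param charge Precursor charge state (>= 1); vectorized.
#' @param label_shift_da Mass difference per label, default the nominal
#'   3 Da ([ACRYLAMIDE_SHIFT_NOMINAL_DA]).
#' @return m/z shift in thomson.
#' @examples
#' expected_heavy_shift(1, 1)  # 3
#' expected_heavy_shift(2, 2)  # 3
#' @export
expected_heavy_shift <- function(n_cys, charge,
                                 label_shift_da = ACRYLAMIDE_SHIFT_NOMINAL_DA) {
  if (any(charge < 1)) {
    abort("`charge` must be >= 1.", class = "mlacdiff_quant_error")
  }
  if (any(n_cys < 1)) {
    abort("Peptide without a cysteine has no isotope label and cannot be quantified.",
          class = "mlacdiff_unquantifiable")
  }
  label_shift_da * n_cys / charge
}

#' Heavy/light ratio from a paired elution profile
#'
#' Integrates the heavy and light extracted elution profiles across the
#' peak by the trapezoidal rule on the provided retention grid and returns
#' the ratio of the areas. This is the relative-abundance measurement of a
#' labeled peptide in one sample against the reference pool.
#'
#' @param rt Strictly increasing retention times (minutes).
#' @param light,heavy Nonnegative intensities at each grid point.
#' @return The dimensionless H/L ratio, heavy area / light area.
#' @examples
#' rt <- seq(0, 2, length.out = 21)
#' prof <- dnorm(rt, 1, 0.2)
#' integrate_pair(rt, prof, 2 * prof)  # 2
#' @export
integrate_pair <- function(rt, light, heavy) {
  if (length(rt) < 2L || length(light) != length(rt) || length(heavy) != length(rt)) {
    abort("`rt`, `light` and `heavy` must be equal-length vectors (>= 2 points).",
          class = "mlacdiff_quant_error")
  }
  if (any(diff(rt) <= 0)) {
    abort("`rt` must be strictly increasing.", class = "mlacdiff_quant_error")
  }
  if (any(light < 0) || any(heavy < 0)) {
    abort("Intensities must be nonnegative.", class = "mlacdiff_quant_error")
  }
  light_area <- pracma::trapz(rt, light)
  if (light_area <= 0) {
    abort("Light profile has zero integrated area; H/L ratio undefined.",
          class = "mlacdiff_zero_light_area")
  }
  pracma::trapz(rt, heavy) / light_area
}

#' Precursor mass-accuracy filter
#'
#' Keeps an observation iff its fractional precursor delta mass is strictly
#' below `tol_ppm` parts per million. The comparison is done as
#' `|observed - theoretical| * 1e6 < tol_ppm * theoretical`, which decides
#' boundary cases by exact arithmetic rather than a rounded division.
#'
#' @param observed_mass,theoretical_mass Precursor masses in Da; vectorized.
#' @param tol_ppm Tolerance in ppm (default 20, strict).
#' @return Logical vector: `TRUE` = keep.
#' @examples
#' ppm_filter(1000.0, 1000.0)          # TRUE  (0 ppm)
#' ppm_filter(500010, 500000)          # FALSE (exactly 20 ppm)
#' @export
ppm_filter <- function(observed_mass, theoretical_mass, tol_ppm = 20) {
  if (any(theoretical_mass <= 0)) {
    abort("`theoretical_mass` must be positive.", class = "mlacdiff_quant_error")
  }
  abs(observed_mass - theoretical_mass) * 1e6 < tol_ppm * theoretical_mass
}

#' Fractional precursor mass error in ppm
#'
#' @inheritParams ppm_filter
#' @return Signed error in parts per million.
#' @export
mass_error_ppm <- function(observed_mass, theoretical_mass) {
  (observed_mass - theoretical_mass) / theoretical_mass * 1e6
}

#' Quantify a table of isotope elution pairs
#'
#' Applies the precursor mass-accuracy filter and the elution-integrated
#' area ratio to each pair. Pairs failing a check are retained in the
#' output with an `NA` ratio and a `drop_reason` (`"ppm_filter"` or
#' `"zero_light_area"`) so no observation is silently discarded.
#'
#' @param pairs Tibble as produced by [generate_elution_pairs()] (or read
#'   by [read_elution_pairs()]): list-columns `rt`, `light`, `heavy` plus
#'   `observed_mass`, `theoretical_mass`.
#' @param tol_ppm Mass-accuracy tolerance in ppm (strict).
#' @return The input tibble with `hl_ratio` and `drop_reason` columns
#'   added; list-columns are dropped.
#' @examples
#' pairs <- generate_elution_pairs(cohort_design(seed = 3), n_pairs = 10)
#' quantify_pairs(pairs) %>% dplyr::count(drop_reason)
#' @export
quantify_pairs <- function(pairs, tol_ppm = 20) {
  stopifnot(all(c("rt", "light", "heavy", "observed_mass", "theoretical_mass")
                %in% names(pairs)))
  keep <- ppm_filter(pairs$observed_mass, pairs$theoretical_mass, tol_ppm)
  ratio <- rep(NA_real_, nrow(pairs))
  reason <- rep(NA_character_, nrow(pairs))
  reason[!keep] <- "ppm_filter"
  for (i in which(keep)) {
    r <- tryCatch(
      integrate_pair(pairs$rt[[i]], pairs$light[[i]], pairs$heavy[[i]]),
      mlacdiff_zero_light_area = function(e) NA_real_
    )
    if (is.na(r)) reason[i] <- "zero_light_area"
    ratio[i] <- r
  }
  pairs %>%
    dplyr::select(-dplyr::where(is.list)) %>%
    dplyr::mutate(hl_ratio = ratio, drop_reason = reason)
}
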