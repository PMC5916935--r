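---
title: "Differential glycoform analysis of lectin-fractionated serum proteomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential glycoform analysis of lectin-fractionated serum proteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlacdiff)
library(dplyr)
```

## The measurement model

mlacdiff analyses serum glycoproteomics experiments in which intact
proteins are separated by multi-lectin affinity chromatography (M-LAC)
before digestion and LC-MS/MS. Three fractions are collected per sample:
the unbound flow-through (**UNB**, non- or otherwise-glycosylated forms),
proteins bound by *Aleuria aurantia* lectin (**AAL**, core-fucosylated
glycoforms) and proteins bound by *Phaseolus vulgaris* L/E agglutinins
(**PHA**, highly branched complex-type glycoforms). Because the separation
happens at the intact-protein level, each fraction carries a distinct
glycoform population of the same gene product, and differential expression
can be assessed per glycoform as well as per protein.

Quantitation is relative to a common reference pool. Case samples are
alkylated with 1,2,3-^13^C~3~ (heavy) acrylamide on cysteines and the
reference pool with ^12^C~3~ (light) acrylamide, so each labeled cysteine
shifts the peptide by a nominal 3 Da. For a peptide with $k$ cysteines at
charge $z$ the heavy form sits $3k/z$ Th above the light form
(`expected_heavy_shift()`; the exact ^13^C~3~–^12^C~3~ difference,
3.0100645 Da, is exported as `ACRYLAMIDE_SHIFT_EXACT_DA` but the nominal
value is used throughout, matching how the shift is conventionally
described). The heavy/light (H/L) ratio of a peptide is the ratio of the
heavy and light elution profiles integrated across the peak
(`integrate_pair()`, trapezoidal rule on the supplied retention grid).
Quantification is restricted to cysteine-containing peptides, and to
observations whose precursor fractional delta mass is strictly below
20 ppm (`ppm_filter()`; the boundary case is decided by exact arithmetic,
`|obs − theo| · 10^6 < tol · theo`).

## From peptides to the quantification matrix

Peptide evidence is filtered on identification confidence (protein-group
probability > 0.9 **and** peptide probability > 0.6, both strict), protein
groups are merged by shared gene names with a deterministic representative
(the lexicographically smallest name in the merged component — the choice
of representative is arbitrary in principle, so we fix a reproducible
rule), and peptide H/L ratios are averaged per (gene, sample, fraction).
The **global** protein level pools all quantified peptides of a gene
across fractions and averages them; it is *not* the mean of fraction
means, so fractions contributing more peptides carry more weight. The
alternative reading (mean of fraction means) is available via
`rollup_evidence(global = "mean_of_means")` but is not the default,
because the pooled-peptide definition follows directly from "an average of
all quantitated peptides regardless of fraction". Averaging happens on the
linear ratio scale *before* the log transform; the order matters and is
fixed here because protein-level ratios are conventionally averaged as
ratios.

Protein-level ratios are then log~2~-transformed and median-centered per
sample: the offset is the median of the sample's fraction-level values
(all three fractions pooled), and the same offset is subtracted from the
sample's global entries. After centering, every sample's pooled
fraction-level median is zero to machine precision, and the centering is
idempotent. Missing entries remain absent — nothing is imputed — and all
downstream sample counting uses presence.

One consequence of median-centering worth knowing: if differential
features make up a substantial share of all features in a sample, the
per-sample median itself moves and group differences of *other* features
absorb the opposite shift. With realistic feature counts (tens to hundreds
of proteins per fraction) and sparse effects this bias is negligible; the
package's simulations use 30–40 proteins or more for this reason.

## Permutation inference

For each (gene, level) feature with at least 3 quantified samples in both
groups (levels are UNB, AAL, PHA and GLOBAL), the group contrast is

$$\Delta = \overline{\log_2 H/L}_{\mathrm{PCa}} - \overline{\log_2 H/L}_{\mathrm{BPH}},$$

tested with a two-sided permutation Welch $t$-test. The Welch statistic
uses unbiased variances; when both group variances vanish the statistic is
0 for equal means and a signed infinity otherwise, which the permutation
layer handles naturally. Group labels are permuted **within the samples
actually observed for that feature** (per-feature $n$ varies because of
missingness). Whenever the number of distinct relabelings
$\binom{n_x+n_y}{n_x}$ is at most `perm_cap` (default 100,000), the test
enumerates all of them — for the default 7-vs-10 cohort that is
$\binom{17}{7} = 19{,}448$, so the test is exact and consumes no
randomness. Beyond the cap, `n_perm` Monte Carlo relabelings are drawn and
the $+1/+1$ correction keeps the p-value positive. Sidedness is not a free
choice here: both over- and under-expressed proteins are reported, so the
test is two-sided via $|t|$. Ties between permuted and observed statistics
are counted using a small relative tolerance so algebraically tied
relabelings are never lost to floating-point rounding.

The FDR is estimated from the same permutation scheme: for each feature,
randomly sampled relabelings are scored against the feature's own null
distribution of $|t|$, giving null p-values that are exchangeable with the
observed one; then

$$\widehat{\mathrm{FDR}}(t) = \frac{\mathbb{E}_{\mathrm{perm}}\,\#\{p_{\mathrm{null}} \le t\}}{\max(1, \#\{p_{\mathrm{obs}} \le t\})},$$

clipped to $[0,1]$ and monotonized by a running minimum from the largest
p-value downward. The raw, unmonotonized value is reported alongside
(`fdr_raw`) for transparency. By default the FDR is computed separately
per level; pooling across levels is available with
`fdr_scope = "pooled"` (which of the two the original analysis used is not
documented, so the more conservative per-level stratification is the
default). Two gates are reported separately rather than conflated:
`significant` ($p \le 0.05$, the convention used for pattern
classification) and `de_pass` (FDR $\le$ 0.01, the differential
quantification bound); `fc_flag` marks features whose |PCa group mean
log~2~ H/L| is at least $\log_2 1.5 = 0.585$, the fold-change inclusion
gate (applied to the absolute value — sidedness of this gate is likewise
not documented, and down-regulation is as reportable as up-regulation).

## Glycoform patterns

Each gene's cross-level significance profile is classified into pattern
groups by a first-match precedence rule (A, B, D, E, F, C, NONE):
A = quantitated and significant in all three fractions; B = significant in
every fraction it was quantitated in (fewer than three); D = significant
in ≥ 2 fractions otherwise; E = exactly one significant fraction plus a
significant global level; F = exactly one significant fraction and a
non-significant global level; C = significant only globally. The
precedence order resolves overlaps that a purely verbal definition leaves
open (a gene significant in all three fractions also meets the definition
of D; the most specific label wins). Group A is decided by the fractions
alone: a gene significant in all three fractions whose opposing trends
cancel at the global level is still A, and such genes are recognizable in
the output by `sig_global = FALSE`. `delta_table()` and `plot_delta()`
produce the per-gene $\Delta$ summary with significance asterisks;
`heatmap_matrix()` builds the gene × (fraction + global) group-mean
matrix, rows ordered by the PCa global mean, with cells blank when a group
has fewer than three observations or the glycoform was never detected
there.

## The synthetic cohort

The raw study data are not publicly deposited, so the package ships a
generator (`generate_cohort()`) that emulates the study design: 7 BPH and
10 PCa samples, each quantified against an implicit reference pool;
proteins occupying each lectin fraction with configurable probabilities
(defaults 0.80/0.55/0.55 for UNB/AAL/PHA — serum proteins are
preferentially seen in the flow-through, glycoforms in the bound fractions
less often); per-gene baseline log~2~ ratios versus the reference drawn
from Normal(0, 0.5); injected effects (`effect_spec()`) that shift the PCa
group by a stated $\Delta$ either globally or within one fraction; and a
hierarchical noise model in which the per-(gene, fraction, sample) latent
value and each peptide observation independently receive Normal(0,
`noise_sd`) noise on the log~2~ scale (default 0.4). Peptides draw 0–3
cysteines uniformly; zero-cysteine peptides are generated and then
excluded from the quantifiable output, so the label constraint is
exercised rather than assumed — a protein can (rarely) be entirely
unquantifiable, as in the real measurement. Observations drop out
independently with probability `missing_rate` (default 0.15), and a small
fraction of rows (default 5%) carry sub-threshold identification
probabilities to exercise the confidence filter. The original study
characterizes neither its noise nor its missingness distribution, so these
defaults are stated assumptions chosen to be realistic for serum
LC-MS/MS, not estimates from the study.

What the generator deliberately does **not** emulate: retention drift,
intensity-dependent detection (dropout is independent of abundance),
correlated peptide interference, and the 13 reversed-phase fractions per
lectin fraction (a depth-of-coverage dimension recorded in the run
manifest — 13 × 3 = 39 fraction slots per sample — but irrelevant to the
statistical model). Passing tests on synthetic data therefore demonstrate
correctness of the computational pipeline under the stated model, not
robustness to every pathology of real spectra.

Every random quantity flows from `design$seed`, so identical designs give
byte-identical cohorts; the returned `truth` object (realized effects plus
every latent value) supports exact end-to-end verification at zero noise
and parameter-recovery measurements under noise.

## Worked example

```{r example, eval = FALSE}
design <- cohort_design(
  n_proteins = 40, noise_sd = 0.5, seed = 1,
  effects = list(effect_spec("GENE0001", "PHA", delta_log2 = 1.5))
)
cohort <- generate_cohort(design)
quant <- quantify_evidence(cohort$evidence)
fit <- compare_groups(quant, seed = 1)
tidy(fit) %>% filter(gene == "GENE0001")
classify_patterns(fit) %>% count(group_label)
autoplot(fit)
```

Or as one orchestrated, manifest-logged run:

```{r pipeline, eval = FALSE}
run <- run_pipeline(pipeline_config(design = design, out_dir = "run1", seed = 1))
run$manifest$fraction_slots_per_sample  # 39
```

## Numerical and design choices

* **Problem sizes.** The calibration suite uses 2,000 null replicates of
  the 7-vs-10 exhaustive test for the type-I error rate and 200 synthetic
  cohorts of 40 proteins for recovery of a fraction-specific
  $\Delta = 1.5$ at `noise_sd = 0.5`; these sizes give binomial standard
  errors comfortably below the tolerances being checked.
* **Elution profiles** are Gaussian over a fixed grid; the heavy profile
  is the light profile scaled by the true ratio with mean-one lognormal
  point noise, so the integrated ratio is unbiased by construction. Any
  unimodal shape would do for testing an area-ratio quantifier; no
  baseline subtraction or smoothing is performed because the synthetic
  profiles are baseline-free.
* **Degenerate inputs.** Zero light area is a classed error and the
  observation is dropped upstream with a logged reason; non-positive H/L
  ratios are a hard error naming the offending row (log2 must be defined);
  all-equal data yield $p = 1$; features absent from a group are blank,
  never zero.
* **Exclusion accounting.** The pipeline manifest counts rows removed by
  the confidence filter and features failing the $n \ge 3$ eligibility
  rule; nothing is dropped silently.

## Limitations

The permutation FDR estimator assumes the sampled relabelings are
exchangeable with the observed labeling under the null; with very few
eligible features the estimate is coarse. Pattern classification treats a
level with no eligible comparison as "not significant", which conflates
"not detected" with "no evidence of change" — the `quantitated_fractions`
column preserves the distinction. The cohort generator's independence
assumptions (peptide noise, dropout) make power estimates on synthetic
data optimistic relative to real serum data with correlated interferences.
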