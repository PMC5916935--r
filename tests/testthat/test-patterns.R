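frac_set <- c("UNB", "AAL", "PHA")

## Build a comparison table for one gene from its quantitated fractions,
## the significant subset, and global significance (NA = global ineligible).
gene_comparisons <- function(gene, quant, sig, sig_global) {
  rows <- lapply(frac_set, function(f) {
    if (f %in% quant) {
      make_comparison(gene, f, p = if (f %in% sig) 0.01 else 0.4)
    } else {
      make_comparison(gene, f, p = NA_real_, eligible = FALSE)
    }
  })
  g <- if (is.na(sig_global)) {
    make_comparison(gene, "GLOBAL", p = NA_real_, eligible = FALSE)
  } else {
    make_comparison(gene, "GLOBAL", p = if (sig_global) 0.01 else 0.4)
  }
  dplyr::bind_rows(c(rows, list(g)))
}

test_that("named expression-pattern examples classify as expected", {
  cmp <- dplyr::bind_rows(
    gene_comparisons("CD5L", quant = frac_set, sig = frac_set,
                     sig_global = TRUE),                       # A
    gene_comparisons("KNG1", quant = frac_set, sig = frac_set,
                     sig_global = FALSE),                      # still A
    gene_comparisons("CD163", quant = c("AAL", "PHA"),
                     sig = c("AAL", "PHA"), sig_global = TRUE), # B
    gene_comparisons("BST1", quant = frac_set, sig = character(0),
                     sig_global = TRUE),                       # C: global only
    gene_comparisons("CFP", quant = frac_set, sig = c("UNB", "AAL"),
                     sig_global = TRUE),                       # D
    gene_comparisons("APOM", quant = frac_set, sig = "PHA",
                     sig_global = TRUE),                       # E
    gene_comparisons("ATRN", quant = frac_set, sig = "PHA",
                     sig_global = FALSE),                      # F
    gene_comparisons("MINPP1", quant = frac_set, sig = character(0),
                     sig_global = FALSE)                       # NONE
  )
  pat <- classify_patterns(cmp)
  lab <- function(g) as.character(pat$group_label[pat$gene == g])
  expect_equal(lab("CD5L"), "A")
  expect_equal(lab("KNG1"), "A")
  expect_equal(lab("CD163"), "B")
  expect_equal(lab("BST1"), "C")
  expect_equal(lab("CFP"), "D")
  expect_equal(lab("APOM"), "E")
  expect_equal(lab("ATRN"), "F")
  expect_equal(lab("MINPP1"), "NONE")
})

test_that("classification is total, deterministic and order-invariant", {
  ## every combination of quantitated set, significant subset and global flag
  subsets <- function(x) {
    unlist(lapply(0:length(x), function(k) combn(x, k, simplify = FALSE)),
           recursive = FALSE)
  }
  cases <- list()
  i <- 0
  for (quant in subsets(frac_set)) {
    for (sig in subsets(quant)) {
      for (sg in c(TRUE, FALSE)) {
        i <- i + 1
        cases[[i]] <- list(gene = sprintf("g%03d", i), quant = quant,
                           sig = sig, sg = sg)
      }
    }
  }
  cmp <- dplyr::bind_rows(lapply(cases, function(cs) {
    gene_comparisons(cs$gene, cs$quant, cs$sig, cs$sg)
  }))
  pat <- classify_patterns(cmp)
  expect_equal(nrow(pat), length(cases))            # exactly one label each
  expect_false(anyNA(pat$group_label))

  ## independent restatement of the precedence rule
  expected <- vapply(cases, function(cs) {
    nq <- length(cs$quant); ns <- length(cs$sig)
    if (nq == 3 && ns == 3) "A"
    else if (ns >= 1 && ns == nq) "B"
    else if (ns >= 2) "D"
    else if (ns == 1 && cs$sg) "E"
    else if (ns == 1 && !cs$sg) "F"
    else if (cs$sg) "C"
    else "NONE"
  }, character(1))
  got <- as.character(pat$group_label[match(sprintf("g%03d", seq_along(cases)),
                                            pat$gene)])
  expect_equal(got, expected)

  ## shuffling comparison rows changes nothing
  pat2 <- classify_patterns(cmp[withr::with_seed(3, sample(nrow(cmp))), ])
  expect_equal(dplyr::arrange(pat, gene), dplyr::arrange(pat2, gene))

  ## A-labeled genes are quantitated in all three fractions
  a_genes <- pat$gene[pat$group_label == "A"]
  expect_true(all(pat$quantitated_fractions[pat$gene %in% a_genes] ==
                    "UNB,AAL,PHA"))
})

test_that("delta table carries signed differences with significance flags", {
  cmp <- dplyr::bind_rows(
    make_comparison("SRGN", "UNB", p = 0.003, delta = -1.53 - 1.59),
    make_comparison("SRGN", "GLOBAL", p = 0.2, delta = -1.0),
    make_comparison("EQ", "UNB", p = 1, delta = 0)
  )
  dt <- delta_table(cmp)
  srgn <- dt[dt$gene == "SRGN" & dt$level == "UNB", ]
  expect_equal(srgn$delta, -3.12)
  expect_true(srgn$significant)
  expect_equal(dt$delta[dt$gene == "EQ"], 0)
  expect_false(dt$significant[dt$gene == "EQ"])
})

test_that("delta flips sign when group labels are swapped", {
  co <- generate_cohort(tiny_design())
  q <- quantify_evidence(co$evidence)
  d1 <- delta_table(compare_groups(q, seed = 2, fdr_perms = 0))
  q2 <- dplyr::mutate(q, group = ifelse(group == "PCa", "BPH", "PCa"))
  d2 <- delta_table(compare_groups(q2, seed = 2, fdr_perms = 0))
  merged <- dplyr::inner_join(d1, d2, by = c("gene", "level"))
  expect_equal(merged$delta.x, -merged$delta.y)
})

test_that("heatmap matrix applies the blank rules and the PCa-global ordering", {
  q <- dplyr::bind_rows(
    # detected in AAL only, well-quantified there in both groups
    make_quant("AALONLY", "AAL", bph = rnorm(4), pca = rnorm(5)),
    make_quant("AALONLY", "GLOBAL", bph = rnorm(4), pca = rnorm(5)),
    # strong PCa global mean: should sort first
    make_quant("HIGH", "UNB", bph = rep(0, 3), pca = rep(2, 3)),
    make_quant("HIGH", "GLOBAL", bph = rep(0, 3), pca = rep(2, 3)),
    # n = 2 in BPH PHA: that cell blank, global still present
    make_quant("LOW", "PHA", bph = rnorm(2), pca = rnorm(4)),
    make_quant("LOW", "GLOBAL", bph = rnorm(3), pca = rep(1, 3))
  )
  hm <- heatmap_matrix(q)
  expect_equal(hm$gene[1], "HIGH")                  # 2.0 > 1.0 > AALONLY
  row_aal <- hm[hm$gene == "AALONLY", ]
  expect_false(is.na(row_aal$PCa_AAL))
  expect_true(is.na(row_aal$PCa_UNB) && is.na(row_aal$PCa_PHA))
  row_low <- hm[hm$gene == "LOW", ]
  expect_true(is.na(row_low$BPH_PHA))               # n = 2 < 3
  expect_false(is.na(row_low$PCa_PHA))

  # a gene without global n >= 3 in both groups is excluded entirely
  q2 <- dplyr::bind_rows(q,
    make_quant("THIN", "GLOBAL", bph = rnorm(2), pca = rnorm(5)))
  expect_false("THIN" %in% heatmap_matrix(q2)$gene)
})

test_that("plot builders return ggplot objects", {
  co <- generate_cohort(cohort_design(
    n_proteins = 10, seed = 6,
    effects = list(effect_spec("GENE0002", "AAL", 2))))
  q <- quantify_evidence(co$evidence)
  fit <- compare_groups(q, seed = 6, fdr_perms = 0)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(plot_heatmap(heatmap_matrix(q)), "ggplot")
})
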