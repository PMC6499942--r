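test_that("one-sided exact test matches enumeration and fisher.test", {
  # the fully worked 2x2: upper tail of (1,1;1,1) is 1 - C(2,0)C(2,2)/C(4,2)
  expect_equal(fisher_one_sided(1, 1, 1, 1, direction = "enrichment"), 5 / 6)
  set.seed(41)
  for (r in 1:50) {
    tb <- rpois(4, sample(c(2, 10, 60), 1))
    pu <- fisher_one_sided(tb[1], tb[2], tb[3], tb[4], direction = "enrichment")
    pl <- fisher_one_sided(tb[1], tb[2], tb[3], tb[4], direction = "depletion")
    expect_equal(pu, enum_fisher(tb[1], tb[2], tb[3], tb[4], upper = TRUE),
                 tolerance = 1e-12)
    expect_equal(pl, enum_fisher(tb[1], tb[2], tb[3], tb[4], upper = FALSE),
                 tolerance = 1e-12)
    m <- matrix(c(tb[1], tb[3], tb[2], tb[4]), 2, 2)
    expect_equal(pu, fisher.test(m, alternative = "greater")$p.value,
                 tolerance = 1e-10)
    expect_equal(pl, fisher.test(m, alternative = "less")$p.value,
                 tolerance = 1e-10)
    # the two tails share the observed point, so they sum to at least 1
    expect_gte(pu + pl, 1)
  }
  # zero margins give p = 1
  expect_equal(fisher_one_sided(0, 5, 0, 7), 1)
  expect_equal(fisher_one_sided(3, 0, 4, 0), 1)
  expect_error(fisher_one_sided(-1, 1, 1, 1), "nonnegative")
})

test_that("observed-direction picks the tail toward the sample effect", {
  expect_equal(fisher_one_sided(12, 5588, 3, 6861),
               fisher_one_sided(12, 5588, 3, 6861, direction = "enrichment"))
  expect_equal(fisher_one_sided(2, 1118, 9, 2279),
               fisher_one_sided(2, 1118, 9, 2279, direction = "depletion"))
})

test_that("odds ratios follow the cross-product rule with zero-cell conventions", {
  expect_equal(round(odds_ratio(12, 5588, 3, 6861), 1), 4.9)
  expect_equal(odds_ratio(5, 5, 5, 5), 1)
  expect_equal(odds_ratio(0, 10, 1, 9), 0)
  expect_identical(odds_ratio(1, 9, 0, 10), Inf)
  expect_true(is.na(odds_ratio(0, 10, 0, 10)))
  # conditional-MLE variant delegates to the exact conditional estimate
  expect_equal(odds_ratio(4, 16, 2, 18, conditional = TRUE),
               unname(fisher.test(matrix(c(4, 2, 16, 18), 2, 2))$estimate))
})

test_that("major-allele slots derive from cohort size and variant count", {
  tabs <- table45_counts()
  mj <- burden_majors(tabs[["ABCB5:regulatory"]])
  expect_equal(unname(mj["case_major"]), 2 * 560 * 5 - 12)     # 5588
  expect_equal(unname(mj["control_major"]), 2 * 1144 * 3 - 3)  # 6861
  z <- tabs[["ZFP69B:regulatory"]]
  expect_equal(unname(burden_majors(z)), c(0, 0))
  expect_error(burden_table_from_counts("g", "deleterious", 50, 1, 10, 0, 0, 10))
})

test_that("burden tables from genotypes apply class, rarity and per-cohort rules", {
  ann <- data.frame(
    chrom = "1", pos = c(1L, 2L, 3L, 4L), ref = "A", alt = "G",
    rsid = NA, pop_maf = NA,
    gene = c("G1", "G1", "G1", "G2"),
    func_class = "exonic",
    exonic_class = c("nonsynonymous", "nonsynonymous", "nonsynonymous",
                     "nonsynonymous"),
    sift = c("deleterious", "deleterious", "tolerated", "deleterious"),
    polyphen = c("damaging", "damaging", "damaging", "damaging"),
    gerp = 2, regulome = NA, stringsAsFactors = FALSE)
  keys <- variant_key(ann)
  case_g <- matrix(0, 20, 4, dimnames = list(paste0("ca", 1:20), keys))
  ctrl_g <- matrix(0, 20, 4, dimnames = list(paste0("co", 1:20), keys))
  case_g[1:2, 1] <- 1   # variant 1: cases only (2 copies)
  ctrl_g[1, 2] <- 1     # variant 2: controls only
  case_g[, 3] <- 1      # variant 3: fails the class predicate (tolerated)
  case_g[1, 4] <- 1     # variant 4: other gene
  cases <- list(variants = ann, geno = case_g)
  controls <- list(variants = ann, geno = ctrl_g)
  tb <- build_burden_table("G1", "deleterious", cases, controls)
  expect_equal(tb$case_minor, 2)
  expect_equal(tb$case_variants, 1)    # variant 2 unobserved in cases
  expect_equal(tb$control_minor, 1)
  expect_equal(tb$control_variants, 1)
  expect_equal(unname(burden_majors(tb)), c(2 * 20 * 1 - 2, 2 * 20 * 1 - 1))
  # common variants are excluded by the combined-MAF rule
  case_g2 <- case_g; case_g2[, 1] <- 2  # 20/40 combined
  tb2 <- build_burden_table("G1", "deleterious",
                            list(variants = ann, geno = case_g2), controls)
  expect_equal(tb2$case_variants, 0)
  expect_error(build_burden_table("NOPE", "deleterious", cases, controls),
               "absent")
})

test_that("burden scan reproduces the validation-cohort statistics", {
  sc <- burden_scan(table45_counts())
  pick <- function(g, cl) sc[sc$gene == g & sc$variant_class == cl, ]
  expect_equal(round(pick("ABCB5", "regulatory")$odds_ratio, 1), 4.9)
  expect_equal(round(pick("UVSSA", "deleterious")$odds_ratio, 2), 1.29)
  expect_equal(round(pick("ZFP69B", "deleterious")$odds_ratio, 2), 0.51)
  expect_equal(round(pick("PDIA2", "regulatory")$odds_ratio, 2), 0.85)
  expect_equal(round(pick("KIF2C", "regulatory")$odds_ratio, 2), 0.45)
  # all-zero table excluded from testing and from the multiplier
  zf <- pick("ZFP69B", "regulatory")
  expect_false(zf$testable)
  expect_true(is.na(zf$p_value))
  m_reg <- sum(sc$testable[sc$variant_class == "regulatory"])
  expect_equal(m_reg, 7)
  ab <- pick("ABCB5", "regulatory")
  expect_equal(ab$q_value, min(1, m_reg * ab$p_value))
  # fixed-multiplier convention
  sc8 <- burden_scan(table45_counts(), m = 8)
  ab8 <- sc8[sc8$gene == "ABCB5" & sc8$variant_class == "regulatory", ]
  expect_equal(ab8$q_value, min(1, 8 * ab8$p_value))
  # q is monotone in p and capped at 1
  for (cl in c("deleterious", "regulatory")) {
    part <- sc[sc$variant_class == cl & sc$testable, ]
    expect_true(all(diff(part$q_value) >= -1e-12))
    expect_true(all(part$q_value <= 1))
  }
})

test_that("swapping cohorts inverts the odds ratio and mirrors the tail", {
  tb <- burden_table_from_counts("g", "deleterious", 9, 3, 50, 4, 2, 80)
  swapped <- burden_table_from_counts("g", "deleterious", 4, 2, 80, 9, 3, 50)
  s1 <- burden_scan(list(tb))
  s2 <- burden_scan(list(swapped))
  expect_equal(s1$odds_ratio, 1 / s2$odds_ratio, tolerance = 1e-12)
  expect_equal(s1$p_value, s2$p_value, tolerance = 1e-12)
  expect_false(identical(s1$direction, s2$direction))
})

test_that("pre-aggregated counts round-trip exactly through the TSV", {
  tabs <- table45_counts()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_burden_counts(tabs, f)
  back <- read_burden_counts(f)
  expect_setequal(names(back), names(tabs))
  for (nm in names(tabs))
    expect_identical(unclass(back[[nm]]), unclass(tabs[[nm]]))
})
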