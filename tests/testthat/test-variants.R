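make_vcf <- function(lines, samples = c("s1", "s2")) {
  f <- withr::local_tempfile(fileext = ".vcf", .local_envir = parent.frame())
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    lines), f)
  f
}

test_that("read_vcf counts alternate alleles and decomposes multi-allelics", {
  f <- make_vcf(c(
    paste("1", "100", "rs1", "A", "T", ".", ".", ".", "GT", "0/1", "1/1", sep = "\t"),
    paste("1", "200", ".", "G", "A,T", ".", ".", ".", "GT", "1/2", "./.", sep = "\t")))
  cs <- read_vcf(f)
  expect_identical(colnames(cs$geno), c("1:100:A:T", "1:200:G:A", "1:200:G:T"))
  expect_equal(unname(cs$geno["s1", ]), c(1, 1, 1))
  expect_equal(unname(cs$geno["s2", ]), c(2, NA, NA))
  expect_identical(cs$variants$rsid, c("rs1", NA, NA))
  # two decomposed variants share the position
  expect_identical(cs$variants$pos, c(100L, 200L, 200L))

  expect_error(read_vcf(f, sample_subset = c("s1", "nope")), "not in VCF")
  sub <- read_vcf(f, sample_subset = "s2")
  expect_identical(rownames(sub$geno), "s2")
})

test_that("VCF writing round-trips genotypes and missingness", {
  f <- make_vcf(paste("2", "50", "rs9", "C", "G", ".", ".", ".", "GT",
                      "0/1", "./.", sep = "\t"))
  cs <- read_vcf(f)
  f2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(cs, f2)
  cs2 <- read_vcf(f2)
  expect_identical(cs2$geno, cs$geno)
  expect_equal(cs2$variants$rsid, cs$variants$rsid)
})

test_that("callset intersection requires exact allele match", {
  mk <- function(keys, samples = "s1") {
    parts <- strsplit(keys, ":")
    v <- data.frame(chrom = sapply(parts, `[`, 1),
                    pos = as.integer(sapply(parts, `[`, 2)),
                    ref = sapply(parts, `[`, 3),
                    alt = sapply(parts, `[`, 4), stringsAsFactors = FALSE)
    g <- matrix(1, nrow = length(samples), ncol = length(keys),
                dimnames = list(samples, keys))
    list(variants = v, geno = g)
  }
  a <- mk(c("1:10:A:T", "1:20:C:G"))
  b <- mk(c("1:20:C:G", "1:30:G:A"))
  expect_identical(variant_key(intersect_callsets(a, b)$variants), "1:20:C:G")
  # same position, different alternate allele: excluded
  d <- mk("1:10:A:G")
  expect_identical(nrow(intersect_callsets(a, d)$variants), 0L)
  # identity and commutativity on keys
  expect_identical(variant_key(intersect_callsets(a, a)$variants),
                   variant_key(a$variants))
  expect_setequal(variant_key(intersect_callsets(a, b)$variants),
                  variant_key(intersect_callsets(b, a)$variants))
  # idempotence
  ab <- intersect_callsets(a, b)
  expect_identical(intersect_callsets(ab, b)$variants, ab$variants)
})

test_that("strict intersection drops genotype-discordant sites", {
  v <- data.frame(chrom = "1", pos = 10L, ref = "A", alt = "T",
                  stringsAsFactors = FALSE)
  mk <- function(dos) list(variants = v, geno = matrix(
    dos, 2, 1, dimnames = list(c("s1", "s2"), "1:10:A:T")))
  a <- mk(c(1, 1)); b <- mk(c(1, 2))
  expect_identical(nrow(intersect_callsets(a, b, strict = TRUE)$variants), 0L)
  b2 <- mk(c(1, NA))  # missing is not discordant
  expect_identical(nrow(intersect_callsets(a, b2, strict = TRUE)$variants), 1L)
})

test_that("missing genotypes become homozygous reference, others untouched", {
  g <- matrix(c(NA, 1, NA, 2, 0, NA), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("v1", "v2")))
  out <- missing_to_reference(g)
  expect_equal(unname(out[, "v1"]), c(0, 1, 0))
  expect_equal(unname(out[, "v2"]), c(2, 0, 0))
  full <- matrix(0:1, 2, 1, dimnames = list(c("a", "b"), "v"))
  expect_identical(missing_to_reference(full), full)
})

test_that("categorization matches the three rules on a generated grid", {
  windows <- data.frame(chrom = "1", start = 500L, end = 1500L,
                        stringsAsFactors = FALSE)
  grid <- expand.grid(rsid = c(NA, "rs1"), pop_maf = c(NA, 0.0008, 0.01, 0.02),
                      pos = c(100L, 1000L), stringsAsFactors = FALSE)
  v <- data.frame(chrom = "1", pos = grid$pos, ref = "A", alt = "G",
                  rsid = grid$rsid, pop_maf = grid$pop_maf,
                  stringsAsFactors = FALSE)
  out <- categorize(v, windows, known_rare_maf_max = 0.01)
  for (k in seq_len(nrow(v))) {
    want <- brute_categorize(v$rsid[k], v$pop_maf[k], v$chrom[k], v$pos[k],
                             windows, 0.01)
    expect_identical(out$cat_rare_private[k], want$rare_private)
    expect_identical(out$cat_known_rare[k], want$known_rare)
    expect_identical(out$cat_candidate_gene[k], want$candidate_gene)
    expect_identical(out$category[k], want$primary)
  }
  # the worked examples
  ex <- categorize(data.frame(
    chrom = c("1", "7", "1"), pos = c(100L, 20721130L, 1000L),
    ref = "A", alt = "G",
    rsid = c(NA, "rs139741319", "rs2"),
    pop_maf = c(NA, 0.0008, 0.02), stringsAsFactors = FALSE), windows)
  expect_identical(ex$category, c("rare_private", "known_rare", "candidate_gene"))
})

test_that("candidate windows pad gene spans and convert BED coordinates", {
  w <- candidate_windows(data.frame(chrom = "1", start = 100000L,
                                    end = 101000L, name = "G"), pad_bp = 25000)
  expect_equal(w$start, 100000 - 25000 + 1)
  expect_equal(w$end, 101000 + 25000)
  w0 <- candidate_windows(data.frame(chrom = "1", start = 10L, end = 20L))
  expect_equal(w0$start, 1)  # floored at chromosome start
})

test_that("deleteriousness filter over the full annotation domain", {
  dom <- expand.grid(
    exonic_class = c("stopgain", "stoploss", "nonsynonymous", "synonymous", NA),
    sift = c("deleterious", "tolerated", NA),
    polyphen = c("damaging", "benign", NA),
    gerp = c(2, 4, NA), stringsAsFactors = FALSE)
  v <- cbind(data.frame(chrom = "1", pos = seq_len(nrow(dom)), ref = "A",
                        alt = "G", stringsAsFactors = FALSE), dom)
  for (dir in c("lt", "ge")) {
    got <- classify_deleterious(v, gerp_threshold = 3, gerp_direction = dir)
    want <- with(dom, {
      stopv <- !is.na(exonic_class) & exonic_class %in% c("stopgain", "stoploss")
      scores <- !is.na(sift) & sift == "deleterious" &
        !is.na(polyphen) & polyphen == "damaging" &
        !is.na(gerp) & (if (dir == "lt") gerp < 3 else gerp >= 3)
      stopv | scores
    })
    expect_identical(got, want)
  }
  gotb <- classify_deleterious(v, mode = "burden")
  wantb <- with(dom, {
    stopv <- !is.na(exonic_class) & exonic_class %in% c("stopgain", "stoploss")
    ns <- !is.na(exonic_class) & exonic_class == "nonsynonymous" &
      !is.na(sift) & sift == "deleterious" &
      !is.na(polyphen) & polyphen == "damaging"
    stopv | ns
  })
  expect_identical(gotb, wantb)
})

test_that("regulatory filter keeps RegulomeDB ranks 1 and 2 only", {
  v <- data.frame(chrom = "1", pos = 1:6, ref = "A", alt = "G",
                  regulome = c("1f", "2", "2b", "3", "5", NA),
                  stringsAsFactors = FALSE)
  expect_identical(classify_regulatory(v),
                   c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_identical(regulome_rank(c("1f", "7", "9", NA)),
                   c(1L, 7L, NA, NA))
})

test_that("family MAF reproduces the study's worked examples", {
  cs <- table3_callset()
  expect_equal(round(family_maf(cs$geno, "16:4606552:T:C"), 3), 0.105)  # 4/38
  expect_equal(round(family_maf(cs$geno, "8:145773319:G:A"), 3), 0.079) # 3/38
  expect_equal(family_maf(cs$geno, "16:4606552:T:C"), 4 / 38)
  # no carriers and all homozygous-alt extremes
  g <- matrix(c(0, 0, 2, 2), 2, 2, dimnames = list(c("a", "b"), c("v0", "v2")))
  expect_equal(family_maf(g, "v0"), 0)
  expect_equal(family_maf(g, "v2"), 1)
  expect_error(family_maf(g, "v0", character(0)), "empty sample")
  expect_error(family_maf(g, "missing-key"), "not in genotype")
})
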