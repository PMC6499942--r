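#' The three sarcoma-proband study pedigrees
#'
#' Encodes the three multigenerational cancer-cluster families of the
#' discovery cohort: 19 sequenced members (9 cancer cases, 10 unaffected)
#' plus the relatives needed to close the graph (an ungenotyped spouse in
#' family 2, and the ungenotyped grandfather and breast-cancer aunt in
#' family 3). Family 1 carries a Ewing sarcoma proband (onset 15) and his
#' liposarcoma-affected father (onset 39); family 2 a liposarcoma proband
#' (onset 61), his prostate-cancer father (onset 71) and two melanoma
#' sisters (onsets 44 and 46); family 3 a PNET proband (onset 22), her
#' sarcoma-affected grandmother (onset 79) and prostate-cancer father
#' (onset 51). The proband's non-identical twin in family 1 is an ordinary
#' full sibling for kinship. Sexes and affection reflect the study
#' descriptions; current ages of members without a recorded age are
#' study-consistent synthetic values (sequenced-cohort mean 55.3, range
#' 15-90).
#'
#' @return a `famped` table (20 rows, 19 genotyped).
#' @export
fig1_pedigrees <- function() {
  p1 <- pedigree(
    fid = "1",
    id = c("1-I-1", "1-I-2", "1-II-1", "1-II-2", "1-II-3", "1-III-1", "1-III-2"),
    father = c(NA, NA, "1-I-1", "1-I-1", NA, "1-II-2", "1-II-2"),
    mother = c(NA, NA, "1-I-2", "1-I-2", NA, "1-II-3", "1-II-3"),
    sex = c("male", "female", "female", "male", "female", "male", "male"),
    affected_cancer = c("no", "no", "no", "yes", "no", "yes", "no"),
    affected_sarcoma = c("no", "no", "no", "yes", "no", "yes", "no"),
    age = c(88, 85, 60, 58, 55, 15, 15),
    onset_age = c(NA, NA, NA, 39, NA, 15, NA),
    proband = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    genotyped = TRUE
  )
  p2 <- pedigree(
    fid = "2",
    id = c("2-I-1", "2-I-2", "2-II-1", "2-II-2", "2-II-3", "2-II-4",
           "2-II-5", "2-III-1"),
    father = c(NA, NA, "2-I-2", "2-I-2", "2-I-2", "2-I-2", NA, "2-II-1"),
    mother = c(NA, NA, "2-I-1", "2-I-1", "2-I-1", "2-I-1", NA, "2-II-5"),
    sex = c("female", "male", "male", "female", "female", "female",
            "female", "female"),
    affected_cancer = c("no", "yes", "yes", "yes", "yes", "no", "no", "no"),
    affected_sarcoma = c("no", "no", "yes", "no", "no", "no", "no", "no"),
    age = c(90, 89, 65, 63, 61, 58, NA, 26),
    onset_age = c(NA, 71, 61, 46, 44, NA, NA, NA),
    proband = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    genotyped = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE)
  )
  p3 <- pedigree(
    fid = "3",
    id = c("3-I-1", "3-I-2", "3-II-1", "3-II-2", "3-II-3", "3-III-1",
           "3-III-2"),
    father = c(NA, NA, "3-I-2", NA, "3-I-2", "3-II-1", "3-II-1"),
    mother = c(NA, NA, "3-I-1", NA, "3-I-1", "3-II-2", "3-II-2"),
    sex = c("female", "male", "male", "female", "female", "female", "male"),
    affected_cancer = c("yes", "no", "yes", "no", "yes", "yes", "no"),
    affected_sarcoma = c("yes", "no", "no", "no", "no", "yes", "no"),
    age = c(82, NA, 55, 42, NA, 24, 20),
    onset_age = c(79, NA, 51, NA, 36, 22, NA),
    proband = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    genotyped = c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE)
  )
  rbind(p1, p2, p3)
}

#' The eight prioritized variants and their annotations
#'
#' The eight variants that survived family-based association and
#' segregation in the study, with their reported annotation fields: rsID
#' (none for the private ARHGAP39 variant), reference-population MAF, gene,
#' functional class, SIFT / PolyPhen-2 calls, RegulomeDB category and the
#' family each segregates in. Reference/alternate alleles and GERP scores
#' are synthetic placeholders consistent with the reported classes (the
#' source tables do not print them).
#'
#' @return annotation data frame with an extra `family` column.
#' @export
table3_variants <- function() {
  v <- data.frame(
    chrom = c("8", "16", "7", "1", "4", "16", "1", "16"),
    pos = c(145773319L, 4606552L, 20721130L, 40929077L, 1348920L,
            66503705L, 45224937L, 334543L),
    ref = c("G", "T", "G", "C", "G", "C", "A", "C"),
    alt = c("A", "C", "A", "G", "A", "A", "G", "G"),
    rsid = c(NA, "rs191227556", "rs139741319", "rs139213019", "rs116741007",
             "rs200706119", "rs139373762", "rs45614840"),
    pop_maf = c(NA, 0.0002, 0.0008, 0.0016, 0.0040, 0.0050, 0.0012, 0.05),
    gene = c("ARHGAP39", "C16orf96", "ABCB5", "ZFP69B", "UVSSA", "BEAN1",
             "KIF2C", "PDIA2"),
    func_class = c("exonic", "exonic", "intronic", "exonic", "exonic",
                   "exonic", "intronic", "exonic"),
    exonic_class = c("nonsynonymous", "nonsynonymous", NA, "nonsynonymous",
                     "nonsynonymous", "nonsynonymous", NA, "nonsynonymous"),
    sift = c("deleterious", "deleterious", NA, "deleterious", "deleterious",
             "tolerated", NA, "deleterious"),
    polyphen = c("damaging", "damaging", NA, "damaging", "damaging", NA,
                 NA, "damaging"),
    gerp = c(2.5, 2.8, NA, 2.2, 2.6, 1.4, NA, 2.1),
    regulome = c(NA, "2", "2", NA, NA, NA, "2", NA),
    family = c("3", "2", "2", "3", "3", "3", "3", "2"),
    stringsAsFactors = FALSE
  )
  v
}

#' Gene spans for the eight prioritized genes (BED coordinates)
#'
#' Synthetic spans covering each prioritized variant, used to build the
#' padded candidate-gene windows; real gene models are not shipped.
#'
#' @return data frame with `chrom`, `start`, `end`, `name` (BED, 0-based
#'   half-open).
#' @export
table3_gene_spans <- function() {
  v <- table3_variants()
  data.frame(chrom = v$chrom,
             start = pmax(0, v$pos - 5000L),
             end = v$pos + 5000L,
             name = v$gene, stringsAsFactors = FALSE)
}

#' Genotypes of the prioritized variants across the 19 sequenced members
#'
#' Each variant is heterozygous in exactly the affected genotyped members
#' of its family and absent elsewhere — the configuration the strict
#' segregation filter accepts, giving within-family MAFs of 4/38 = 0.105
#' (family 2) and 3/38 = 0.079 (family 3) over the 19 sequenced subjects.
#'
#' @return a callset (`list(variants, geno)`) over the 19 genotyped
#'   samples.
#' @export
table3_callset <- function() {
  ped <- fig1_pedigrees()
  v <- table3_variants()
  ids <- ped$id[ped$genotyped]
  geno <- matrix(0, nrow = length(ids), ncol = nrow(v),
                 dimnames = list(ids, variant_key(v)))
  for (k in seq_len(nrow(v))) {
    carriers <- ped$id[ped$fid == v$family[k] & ped$genotyped &
                         ped$affected_cancer == "yes"]
    geno[carriers, k] <- 1
  }
  list(variants = v[, setdiff(names(v), "family")], geno = geno)
}

#' Published validation-cohort burden counts
#'
#' Minor-allele counts and qualifying-variant counts for the eight
#' prioritized genes in the validation cohorts (560 sarcoma cases, 1144
#' cancer-free controls), for the rare nonsynonymous-deleterious and rare
#' putative-regulatory variant classes. These printed counts are the
#' worked example for the stage-two burden machinery.
#'
#' @return list of `burden_table` objects (one per gene x class).
#' @export
table45_counts <- function() {
  del <- data.frame(
    gene = c("ABCB5", "ARHGAP39", "BEAN1", "C16orf96", "KIF2C", "PDIA2",
             "UVSSA", "ZFP69B"),
    case_minor = c(30, 1, 1, 4, 0, 5, 21, 2),
    case_variants = c(17, 1, 1, 4, 0, 5, 8, 2),
    control_minor = c(32, 3, 0, 12, 1, 1, 25, 16),
    control_variants = c(16, 1, 0, 9, 1, 1, 6, 4),
    stringsAsFactors = FALSE
  )
  reg <- data.frame(
    gene = del$gene,
    case_minor = c(12, 10, 3, 58, 2, 10, 114, 0),
    case_variants = c(5, 3, 1, 3, 1, 1, 4, 0),
    control_minor = c(3, 24, 1, 151, 9, 24, 215, 0),
    control_variants = c(3, 4, 1, 3, 1, 1, 4, 0),
    stringsAsFactors = FALSE
  )
  tabs <- list()
  for (k in seq_len(nrow(del))) {
    tabs[[paste0(del$gene[k], ":deleterious")]] <- burden_table_from_counts(
      del$gene[k], "deleterious", del$case_minor[k], del$case_variants[k],
      560, del$control_minor[k], del$control_variants[k], 1144)
    tabs[[paste0(reg$gene[k], ":regulatory")]] <- burden_table_from_counts(
      reg$gene[k], "regulatory", reg$case_minor[k], reg$case_variants[k],
      560, reg$control_minor[k], reg$control_variants[k], 1144)
  }
  tabs
}

#' Write the study fixture bundle
#'
#' Emits the deterministic in-package fixture set to a directory:
#' `pedigrees.ped` (the three families), `family_variants.vcf` (19 samples
#' by 8 prioritized variants), `annotation.tsv`, `gene_spans.bed`,
#' `traits.tsv` (trait table with ascertainment weights at 0) and
#' `burden_counts.tsv` (validation-cohort counts). Two runs produce
#' byte-identical files.
#'
#' @param outdir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_fixture_bundle <- function(outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ped <- fig1_pedigrees()
  cs <- table3_callset()
  paths <- c(
    ped = file.path(outdir, "pedigrees.ped"),
    vcf = file.path(outdir, "family_variants.vcf"),
    annotation = file.path(outdir, "annotation.tsv"),
    gene_spans = file.path(outdir, "gene_spans.bed"),
    traits = file.path(outdir, "traits.tsv"),
    burden_counts = file.path(outdir, "burden_counts.tsv")
  )
  write_ped(ped, paths["ped"])
  write_vcf(cs, paths["vcf"])
  an <- table3_variants()
  write_annotation(an[, setdiff(names(an), "family")], paths["annotation"])
  spans <- table3_gene_spans()
  writeLines(paste(spans$chrom, spans$start, spans$end, spans$name,
                   sep = "\t"), paths["gene_spans"])
  write_traits(trait_table(ped), paths["traits"])
  write_burden_counts(table45_counts(), paths["burden_counts"])
  invisible(paths)
}
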