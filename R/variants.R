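#' @title Variant tables and genotype matrices
#' @description Variants are plain data frames with one decomposed
#'   (biallelic) alternate allele per row and the annotation columns
#'   `chrom, pos, ref, alt, rsid, pop_maf, gene, func_class, exonic_class,
#'   sift, polyphen, gerp, regulome`. Genotypes are a samples x variants
#'   integer matrix of minor-allele dosages in `{0, 1, 2}` (or `NA` before
#'   missing-to-reference), with sample ids as row names and variant keys
#'   as column names.
#' @name variant-containers
NULL

#' Variant key
#'
#' Canonical `chrom:pos:ref:alt` key identifying a decomposed variant.
#' Callset intersection uses exact equality of these keys.
#'
#' @param v variant data frame.
#' @return character vector of keys.
#' @export
variant_key <- function(v) {
  paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
}

annotation_cols <- c("rsid", "pop_maf", "gene", "func_class", "exonic_class",
                     "sift", "polyphen", "gerp", "regulome")

# Ensure all annotation columns exist (NA where absent).
pad_annotation <- function(v) {
  for (cl in annotation_cols) {
    if (is.null(v[[cl]])) {
      v[[cl]] <- if (cl %in% c("pop_maf", "gerp")) NA_real_ else NA_character_
    }
  }
  v
}

#' Intersect two callsets by exact allele match
#'
#' Keeps variants present in both callsets under exact
#' `(chrom, pos, ref, alt)` equality — the same position with a different
#' alternate allele does not match. Genotypes are taken from one caller
#' (`a` by default); in strict mode, samples are additionally required to
#' agree between callers at each kept site, and discordant sites are
#' dropped.
#'
#' @param a,b callsets: lists with elements `variants` (data frame) and
#'   `geno` (dosage matrix keyed by [variant_key()]).
#' @param genotypes_from `"a"` or `"b"`.
#' @param strict drop variants with any discordant non-missing genotype.
#' @return a callset with the common variants.
#' @export
intersect_callsets <- function(a, b, genotypes_from = c("a", "b"),
                               strict = FALSE) {
  genotypes_from <- match.arg(genotypes_from)
  ka <- variant_key(a$variants)
  kb <- variant_key(b$variants)
  common <- intersect(ka, kb)
  keep <- ka %in% common
  src <- if (genotypes_from == "a") a else b
  ks <- variant_key(src$variants)
  sel <- ks %in% common
  variants <- src$variants[sel, , drop = FALSE]
  geno <- src$geno[, ks[sel], drop = FALSE]
  if (strict) {
    ga <- a$geno[, common, drop = FALSE]
    gb <- b$geno[rownames(ga), common, drop = FALSE]
    disc <- colSums(!is.na(ga) & !is.na(gb) & ga != gb) > 0
    ok <- common[!disc]
    variants <- variants[variant_key(variants) %in% ok, , drop = FALSE]
    geno <- geno[, variant_key(variants), drop = FALSE]
  }
  rownames(variants) <- NULL
  list(variants = variants, geno = geno)
}

#' Set missing genotypes to homozygous reference
#'
#' Replaces every missing dosage with 0 (the merged-callset convention of
#' treating an uncalled position as homozygous reference); non-missing
#' values are untouched.
#'
#' @param geno dosage matrix.
#' @return dosage matrix without missing values.
#' @export
missing_to_reference <- function(geno) {
  if (anyNA(geno)) geno[is.na(geno)] <- 0
  geno
}

#' Assign prioritization categories to variants
#'
#' Three overlapping categories drive stage-one prioritization:
#' \describe{
#'   \item{rare_private}{no rsID — absent from the variant database build.}
#'   \item{known_rare}{has an rsID and population MAF at or below
#'     `known_rare_maf_max` (default 1\%).}
#'   \item{candidate_gene}{falls inside a candidate-gene window (gene span
#'     padded by `pad_bp` on both sides).}
#' }
#' All matching labels are recorded (`cat_*` logical columns); the single
#' `category` column reports the primary label under the precedence
#' rare_private > known_rare > candidate_gene, or `"none"`.
#'
#' @param v variant data frame.
#' @param windows candidate windows: data frame with `chrom`, `start`,
#'   `end` (1-based inclusive), e.g. from [candidate_windows()].
#' @param known_rare_maf_max MAF ceiling for the known-rare category.
#' @return `v` with `cat_rare_private`, `cat_known_rare`,
#'   `cat_candidate_gene` and `category` columns added.
#' @export
categorize <- function(v, windows = NULL, known_rare_maf_max = 0.01) {
  v <- pad_annotation(v)
  v$cat_rare_private <- is.na(v$rsid)
  v$cat_known_rare <- !is.na(v$rsid) & !is.na(v$pop_maf) &
    v$pop_maf <= known_rare_maf_max
  inwin <- rep(FALSE, nrow(v))
  if (!is.null(windows) && nrow(windows)) {
    for (k in seq_len(nrow(windows))) {
      inwin <- inwin | (v$chrom == windows$chrom[k] &
                          v$pos >= windows$start[k] & v$pos <= windows$end[k])
    }
  }
  v$cat_candidate_gene <- inwin
  v$category <- ifelse(v$cat_rare_private, "rare_private",
                ifelse(v$cat_known_rare, "known_rare",
                ifelse(v$cat_candidate_gene, "candidate_gene", "none")))
  v
}

#' Candidate-gene windows from gene spans
#'
#' Pads each gene span by `pad_bp` on both sides (to capture nearby
#' regulatory variants in off-target reads) and converts BED half-open
#' 0-based spans to 1-based inclusive windows. Padding is applied to the
#' BED ends before conversion; starts are floored at position 1.
#'
#' @param gene_bed data frame with `chrom`, `start`, `end` (BED
#'   coordinates) and optionally `name`, e.g. from [read_bed()].
#' @param pad_bp padding in base pairs (default 25 kb).
#' @return data frame with `chrom`, `start`, `end` (1-based inclusive) and
#'   `name`.
#' @export
candidate_windows <- function(gene_bed, pad_bp = 25000) {
  data.frame(
    chrom = gene_bed$chrom,
    start = pmax(1, gene_bed$start - pad_bp + 1),
    end = gene_bed$end + pad_bp,
    name = if (is.null(gene_bed$name)) NA_character_ else gene_bed$name,
    stringsAsFactors = FALSE
  )
}

#' Deleteriousness filter
#'
#' In `"filter"` mode (the stage-one annotation filter) a variant passes if
#' it is stop-gain or stop-loss, or if SIFT calls it deleterious, PolyPhen-2
#' calls it damaging and its GERP conservation score satisfies the
#' configured comparison. In `"burden"` mode (the stage-two qualifying-
#' variant definition) a variant passes if it is stop-gain/stop-loss or a
#' nonsynonymous change called deleterious by both SIFT and PolyPhen-2;
#' GERP is not consulted. A missing annotation field fails the clause it
#' belongs to.
#'
#' The default GERP comparison keeps scores strictly below
#' `gerp_threshold`, following the source protocol literally. Note that
#' GERP conventionally flags constrained (putatively deleterious) sites at
#' *high* scores, so `gerp_direction = "ge"` is the conventional choice;
#' both are supported and the default is a faithful, documented reading
#' rather than a guess at intent.
#'
#' @param v variant data frame.
#' @param gerp_threshold GERP rejected-substitution score threshold.
#' @param gerp_direction `"lt"` (score < threshold passes) or `"ge"`.
#' @param mode `"filter"` or `"burden"` (see above).
#' @return logical vector.
#' @export
classify_deleterious <- function(v, gerp_threshold = 3,
                                 gerp_direction = c("lt", "ge"),
                                 mode = c("filter", "burden")) {
  gerp_direction <- match.arg(gerp_direction)
  mode <- match.arg(mode)
  v <- pad_annotation(v)
  stop_var <- !is.na(v$exonic_class) & v$exonic_class %in% c("stopgain", "stoploss")
  both_del <- !is.na(v$sift) & v$sift == "deleterious" &
    !is.na(v$polyphen) & v$polyphen == "damaging"
  if (mode == "filter") {
    gerp_ok <- !is.na(v$gerp) &
      (if (gerp_direction == "lt") v$gerp < gerp_threshold
       else v$gerp >= gerp_threshold)
    stop_var | (both_del & gerp_ok)
  } else {
    ns <- !is.na(v$exonic_class) & v$exonic_class == "nonsynonymous"
    stop_var | (ns & both_del)
  }
}

#' Regulatory-evidence filter
#'
#' A variant qualifies as putatively regulatory when the leading integer of
#' its RegulomeDB category (e.g. `"1f"`, `"2"`) is at most `max_rank`;
#' lower ranks carry stronger evidence that the site is functional.
#' Missing categories fail.
#'
#' @param v variant data frame.
#' @param max_rank highest qualifying rank (default 2, i.e. "score < 3").
#' @return logical vector.
#' @export
classify_regulatory <- function(v, max_rank = 2) {
  v <- pad_annotation(v)
  rank <- regulome_rank(v$regulome)
  !is.na(rank) & rank <= max_rank
}

#' Leading integer of a RegulomeDB category string
#' @param x character vector like `"1f"`, `"2"`, `"5"`.
#' @return integer rank (NA where missing or unparseable).
#' @export
regulome_rank <- function(x) {
  r <- suppressWarnings(as.integer(sub("^([0-9]+).*$", "\\1", x)))
  r[!is.na(r) & (r < 1 | r > 7)] <- NA_integer_
  r
}

#' Within-family minor allele frequency
#'
#' Minor-allele dosage summed over the given samples divided by twice the
#' sample count — the "family MAF" reported alongside each prioritized
#' variant. With the 19 sequenced family members as denominator, 4
#' heterozygous carriers give 4/38 = 0.105 and 3 carriers give 3/38 =
#' 0.079.
#'
#' @param geno dosage matrix (missing values must be resolved first).
#' @param key variant key (column of `geno`).
#' @param samples sample ids to include.
#' @return allele frequency in `[0, 1]`.
#' @export
family_maf <- function(geno, key, samples = rownames(geno)) {
  if (length(samples) == 0) stop("family_maf: empty sample list")
  if (!key %in% colnames(geno)) stop("variant not in genotype matrix: ", key)
  d <- geno[samples, key]
  if (anyNA(d)) stop("family_maf: unresolved missing genotypes (apply missing_to_reference)")
  sum(d) / (2 * length(samples))
}
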