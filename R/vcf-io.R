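#' Read a multi-sample VCF into a variant table and dosage matrix
#'
#' Parses a VCF (v4.2) with vcfR, decomposes multi-allelic records into one
#' biallelic row per alternate allele, and counts each alternate allele per
#' sample into a dosage matrix (`NA` where the genotype is missing).
#' Annotation fields can be joined from a side table keyed by
#' `(chrom, pos, ref, alt)` (see [read_annotation()]).
#'
#' @param path VCF path (plain text or bgzipped).
#' @param sample_subset optional character vector of sample ids to keep;
#'   unknown ids are an error.
#' @param annotation optional annotation data frame to join.
#' @return a callset: `list(variants = <data frame>, geno = <matrix>)`.
#' @export
read_vcf <- function(path, sample_subset = NULL, annotation = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(vcf@gt) == 0 || !"FORMAT" %in% colnames(vcf@gt))
    stop("VCF has no genotype (FORMAT/GT) section: ", path)
  has_gt <- vapply(strsplit(vcf@gt[, "FORMAT"], ":"),
                   function(f) "GT" %in% f, logical(1))
  if (any(!has_gt))
    stop("record(s) without GT field at row(s): ",
         paste(utils::head(which(!has_gt), 5), collapse = ", "))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  if (!is.null(sample_subset)) {
    missing <- setdiff(sample_subset, samples)
    if (length(missing))
      stop("sample(s) not in VCF: ", paste(missing, collapse = ", "))
    gt <- gt[, sample_subset, drop = FALSE]
    samples <- sample_subset
  }
  rows <- list(); dos <- list()
  for (k in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[k], ",", fixed = TRUE)[[1]]
    codes <- strsplit(gsub("|", "/", gt[k, ], fixed = TRUE), "/", fixed = TRUE)
    for (a in seq_along(alts)) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix$CHROM[k], pos = as.integer(fix$POS[k]),
        ref = fix$REF[k], alt = alts[a],
        rsid = if (is.na(fix$ID[k]) || fix$ID[k] == ".") NA_character_ else fix$ID[k],
        stringsAsFactors = FALSE
      )
      dos[[length(dos) + 1L]] <- vapply(codes, function(g) {
        if (length(g) == 0 || anyNA(g) || any(g == ".")) return(NA_real_)
        sum(g == as.character(a))
      }, numeric(1))
    }
  }
  variants <- do.call(rbind, rows)
  geno <- do.call(cbind, dos)
  rownames(geno) <- samples
  colnames(geno) <- variant_key(variants)
  variants <- pad_annotation(variants)
  if (!is.null(annotation)) {
    idx <- match(variant_key(variants), variant_key(annotation))
    for (cl in setdiff(annotation_cols, "rsid")) {
      if (!is.null(annotation[[cl]]))
        variants[[cl]] <- annotation[[cl]][idx]
    }
    # the VCF ID column wins; annotation fills rsid only where ID was "."
    if (!is.null(annotation$rsid)) {
      fill <- is.na(variants$rsid)
      variants$rsid[fill] <- annotation$rsid[idx][fill]
    }
  }
  list(variants = variants, geno = geno)
}

#' Write a callset as a plain-text VCF v4.2
#'
#' Dosages map back to unphased diploid genotypes (0 = 0/0, 1 = 0/1,
#' 2 = 1/1, `NA` = ./.). Records are written one decomposed allele per
#' line in the input order.
#'
#' @param callset list with `variants` and `geno`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(callset, path) {
  v <- callset$variants
  g <- callset$geno
  samples <- rownames(g)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  keys <- variant_key(v)
  for (k in seq_len(nrow(v))) {
    gts <- g[, keys[k]]
    gts <- ifelse(is.na(gts), "./.", gt_code[as.character(gts)])
    lines <- c(lines, paste(c(
      v$chrom[k], v$pos[k],
      if (is.na(v$rsid[k])) "." else v$rsid[k],
      v$ref[k], v$alt[k], ".", "PASS", ".", "GT", gts
    ), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read / write the variant annotation table
#'
#' Tab-separated with header; columns `chrom, pos, ref, alt, rsid,
#' pop_maf, gene, func_class, exonic_class, sift, polyphen, gerp,
#' regulome`. Empty strings and `NA` read as missing.
#'
#' @param path file path.
#' @return annotation data frame.
#' @export
read_annotation <- function(path) {
  an <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = c("NA", ""),
                          colClasses = "character", quote = "")
  an$pos <- as.integer(an$pos)
  if (!is.null(an$pop_maf)) an$pop_maf <- as.numeric(an$pop_maf)
  if (!is.null(an$gerp)) an$gerp <- as.numeric(an$gerp)
  pad_annotation(an)
}

#' @rdname read_annotation
#' @param an annotation data frame.
#' @export
write_annotation <- function(an, path) {
  utils::write.table(an, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a BED file
#'
#' Minimal 3-6 column BED reader (0-based half-open coordinates are kept
#' as read; see [candidate_windows()] for conversion).
#'
#' @param path file path.
#' @return data frame with `chrom`, `start`, `end` and, when present,
#'   `name`.
#' @export
read_bed <- function(path) {
  bed <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "")
  names(bed)[1:3] <- c("chrom", "start", "end")
  if (ncol(bed) >= 4) names(bed)[4] <- "name"
  bed
}
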