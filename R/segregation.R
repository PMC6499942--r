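#' Familial segregation filter
#'
#' A candidate variant passes the strict segregation filter when three
#' assumptions hold simultaneously: (a) it is private to one family (all
#' carriers belong to a single pedigree); (b) penetrance is complete
#' (every carrier is affected); and (c) every genotyped affected member of
#' the carrier family carries it. Carriers are samples with dosage >= 1
#' (dominant, single-copy model); ungenotyped members are ignored for (b)
#' and (c) since only sequenced members can be checked. A carrier of
#' unknown affection status counts against (b).
#'
#' @param key variant key (column of `geno`).
#' @param geno dosage matrix over genotyped samples (missing resolved).
#' @param ped the `famped` table.
#' @param phenotype `"cancer"` (any cancer diagnosis counts as the
#'   phenotype, the default since the pedigrees mix cancer types) or
#'   `"sarcoma"`.
#' @return list of class `segregation_result`: `key`, `family_id` (set iff
#'   carriers occur in exactly one family), `passes`, `reasons` (subset of
#'   `no_carriers`, `not_single_family`, `unaffected_carrier`,
#'   `affected_noncarrier`).
#' @export
segregation_filter <- function(key, geno, ped,
                               phenotype = c("cancer", "sarcoma")) {
  phenotype <- match.arg(phenotype)
  if (!key %in% colnames(geno)) stop("variant not in genotype matrix: ", key)
  status_col <- if (phenotype == "cancer") "affected_cancer" else "affected_sarcoma"
  ids <- intersect(rownames(geno), ped$id[ped$genotyped])
  dos <- geno[ids, key]
  if (anyNA(dos)) stop("segregation filter requires complete genotypes")
  carriers <- ids[dos >= 1]
  reasons <- character(0)
  family_id <- NA_character_
  if (length(carriers) == 0) {
    reasons <- "no_carriers"
  } else {
    fams <- unique(ped$fid[match(carriers, ped$id)])
    if (length(fams) > 1) {
      reasons <- c(reasons, "not_single_family")
    } else {
      family_id <- fams
    }
    caff <- ped[[status_col]][match(carriers, ped$id)]
    if (any(caff != "yes")) reasons <- c(reasons, "unaffected_carrier")
    if (length(fams) == 1) {
      fam_ids <- ped$id[ped$fid == fams & ped$genotyped &
                          ped[[status_col]] == "yes"]
      fam_ids <- intersect(fam_ids, ids)
      if (!all(fam_ids %in% carriers))
        reasons <- c(reasons, "affected_noncarrier")
    }
  }
  structure(list(key = key, family_id = family_id,
                 passes = length(reasons) == 0, reasons = reasons),
            class = "segregation_result")
}

#' @export
print.segregation_result <- function(x, ...) {
  cat(sprintf("Segregation: %s -> %s", x$key,
              if (x$passes) sprintf("PASS (family %s)", x$family_id)
              else paste("fail:", paste(x$reasons, collapse = ", "))), "\n")
  invisible(x)
}

#' Run the segregation filter over many variants
#'
#' @param keys variant keys.
#' @inheritParams segregation_filter
#' @return data frame with `key`, `family_id`, `passes`, `reasons`
#'   (comma-joined).
#' @export
segregation_scan <- function(keys, geno, ped,
                             phenotype = c("cancer", "sarcoma")) {
  phenotype <- match.arg(phenotype)
  rows <- lapply(keys, function(k) {
    r <- segregation_filter(k, geno, ped, phenotype)
    data.frame(key = r$key, family_id = r$family_id, passes = r$passes,
               reasons = paste(r$reasons, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
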