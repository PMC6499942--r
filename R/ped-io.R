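#' Read a pedigree file
#'
#' Two dialects are supported. The basic LINKAGE dialect has six
#' whitespace-delimited columns (family, id, father, mother, sex,
#' phenotype) with `0` for a missing parent or unknown sex and affection
#' coded 2 = affected, 1 = unaffected, 0 = unknown. The extended dialect is
#' declared by a header line starting with `#` and carries the additional
#' study columns (sarcoma status, ages, proband and genotyped flags) that
#' [write_ped()] emits.
#'
#' @param path file path.
#' @return a `famped` table.
#' @export
read_ped <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty pedigree file: ", path)
  extended <- startsWith(lines[1], "#")
  if (extended) lines <- lines[-1]
  toks <- strsplit(trimws(lines), "[ \t]+")
  want <- if (extended) 11L else 6L
  nf <- lengths(toks)
  if (any(nf != want)) {
    k <- which(nf != want)[1] + as.integer(extended)
    stop(sprintf("malformed pedigree line %d: expected %d fields, found %d",
                 k, want, nf[which(nf != want)[1]]))
  }
  m <- do.call(rbind, toks)
  decode_parent <- function(x) ifelse(x == "0", NA_character_, x)
  decode_sex <- function(x) c(`1` = "male", `2` = "female", `0` = "unknown")[x]
  decode_aff <- function(x) c(`2` = "yes", `1` = "no", `0` = "unknown")[x]
  decode_num <- function(x) suppressWarnings(as.numeric(ifelse(x == "NA", NA, x)))
  sx <- decode_sex(m[, 5])
  if (anyNA(sx)) stop("invalid sex code in pedigree file (use 0/1/2)")
  if (extended) {
    ped <- pedigree(
      fid = m[, 1], id = m[, 2],
      father = decode_parent(m[, 3]), mother = decode_parent(m[, 4]),
      sex = unname(sx),
      affected_cancer = unname(decode_aff(m[, 6])),
      affected_sarcoma = unname(decode_aff(m[, 7])),
      age = decode_num(m[, 8]), onset_age = decode_num(m[, 9]),
      proband = m[, 10] == "1", genotyped = m[, 11] == "1"
    )
  } else {
    ped <- pedigree(
      fid = m[, 1], id = m[, 2],
      father = decode_parent(m[, 3]), mother = decode_parent(m[, 4]),
      sex = unname(sx),
      affected_cancer = unname(decode_aff(m[, 6])),
      affected_sarcoma = "unknown"
    )
  }
  ped
}

#' Write a pedigree file
#'
#' Emits the extended dialect: a `#`-prefixed header followed by eleven
#' whitespace-delimited columns. `read_ped(write_ped(x))` preserves every
#' field.
#'
#' @param ped a `famped` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path) {
  enc_parent <- function(x) ifelse(is.na(x), "0", x)
  enc_sex <- c(male = "1", female = "2", unknown = "0")[ped$sex]
  enc_aff <- function(x) c(yes = "2", no = "1", unknown = "0")[x]
  enc_num <- function(x) ifelse(is.na(x), "NA", format(x, trim = TRUE))
  out <- paste(ped$fid, ped$id, enc_parent(ped$father), enc_parent(ped$mother),
               enc_sex, enc_aff(ped$affected_cancer),
               enc_aff(ped$affected_sarcoma), enc_num(ped$age),
               enc_num(ped$onset_age), as.integer(ped$proband),
               as.integer(ped$genotyped))
  writeLines(c("#fid id father mother sex cancer sarcoma age onset proband genotyped",
               out), path)
  invisible(path)
}
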