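#' Build the trait table from a pedigree table
#'
#' One row per individual with the four outcomes analysed in stage one:
#' age at onset of cancer, age at onset of sarcoma (both set to 0 for
#' unaffected individuals, by construction), any cancer and any sarcoma as
#' 0/1 indicators. Sex is coded male = 1, female = 0 (`NA` when unknown);
#' the ascertainment weight column `w` starts at 0 and is filled by
#' [ascertainment_weights()].
#'
#' @param ped a `famped` table.
#' @return trait data frame.
#' @export
trait_table <- function(ped) {
  aff01 <- function(x) ifelse(x == "yes", 1, ifelse(x == "no", 0, NA))
  any_cancer <- aff01(ped$affected_cancer)
  any_sarcoma <- aff01(ped$affected_sarcoma)
  onset0 <- function(aff) ifelse(!is.na(aff) & aff == 1, ped$onset_age, 0)
  data.frame(
    sample_id = ped$id,
    age_onset_cancer = onset0(any_cancer),
    age_onset_sarcoma = onset0(any_sarcoma),
    any_cancer = any_cancer,
    any_sarcoma = any_sarcoma,
    age = ped$age,
    sex = ifelse(ped$sex == "male", 1, ifelse(ped$sex == "female", 0, NA)),
    w = 0,
    stringsAsFactors = FALSE
  )
}

#' Read / write a trait table TSV
#' @param path file path.
#' @return trait data frame.
#' @export
read_traits <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "NA", colClasses = list(sample_id = "character"))
}

#' @rdname read_traits
#' @param traits trait data frame.
#' @export
write_traits <- function(traits, path) {
  utils::write.table(traits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
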