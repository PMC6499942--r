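#' Read and validate a run configuration
#'
#' YAML configuration with two blocks: `paths` (input files and `outdir`)
#' and `thresholds`, plus `bonferroni_m` (`"testable"` or an integer) and
#' `seed`. Missing thresholds take the study defaults: known-rare MAF
#' ceiling 0.01, burden MAF ceiling 0.05, candidate-window padding 25000
#' bp, alpha 0.05, GERP threshold 3 with direction `"lt"`, RegulomeDB
#' maximum rank 2. Threshold-range violations and missing required paths
#' raise a config error before any computation.
#'
#' @param path YAML file path.
#' @return config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config error: no such config file: ", path)
  raw <- yaml::read_yaml(path)
  defaults <- list(known_rare_maf_max = 0.01, burden_maf_max = 0.05,
                   pad_bp = 25000, alpha = 0.05, gerp_threshold = 3,
                   gerp_direction = "lt", regulome_max_rank = 2)
  th <- utils::modifyList(defaults, if (is.null(raw$thresholds)) list() else raw$thresholds)
  if (th$known_rare_maf_max < 0 || th$known_rare_maf_max > 1 ||
      th$burden_maf_max <= 0 || th$burden_maf_max > 1 ||
      th$pad_bp < 0 || th$alpha <= 0 || th$alpha >= 1 ||
      !th$gerp_direction %in% c("lt", "ge") ||
      th$regulome_max_rank < 1 || th$regulome_max_rank > 7)
    stop("config error: threshold out of range")
  cfg <- list(paths = raw$paths, thresholds = th,
              bonferroni_m = if (is.null(raw$bonferroni_m)) "testable" else raw$bonferroni_m,
              seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed))
  class(cfg) <- "run_config"
  cfg
}

require_paths <- function(cfg, what) {
  for (w in what) {
    p <- cfg$paths[[w]]
    if (is.null(p)) stop("config error: missing required path '", w, "'")
    if (!file.exists(p)) stop("config error: file not found for '", w, "': ", p)
  }
  invisible(TRUE)
}

#' Run stage one: family-based prioritization
#'
#' Executes caller intersection (when two VCFs are given),
#' missing-to-reference, categorization, the four-outcome association
#' scan per category list (Bonferroni within each list), and the
#' segregation filter on nominally associated variants (p below alpha).
#' Writes `association.tsv` (one row per variant x outcome, with family
#' MAF and category), `segregation.tsv`, and `gene_list.txt` (genes of
#' variants passing segregation) under `outdir`. On error, partial
#' outputs are removed.
#'
#' @param cfg a `run_config` (paths needed: `vcf`, optionally `vcf_b`,
#'   `ped`, `annotation`, `gene_spans`, optionally `traits`, and
#'   `outdir`).
#' @return invisibly, a list with `genes`, `association`, `segregation`
#'   and the written paths.
#' @export
run_stage1 <- function(cfg) {
  require_paths(cfg, c("vcf", "ped", "annotation", "gene_spans"))
  if (is.null(cfg$paths$outdir)) stop("config error: missing 'outdir'")
  th <- cfg$thresholds
  set.seed(cfg$seed)
  ped <- read_ped(cfg$paths$ped)
  viol <- validate_pedigree(ped)
  if (length(viol)) stop("stage1: invalid pedigree: ", paste(viol, collapse = "; "))
  an <- read_annotation(cfg$paths$annotation)
  cs <- read_vcf(cfg$paths$vcf, annotation = an)
  if (!is.null(cfg$paths$vcf_b)) {
    require_paths(cfg, "vcf_b")
    csb <- read_vcf(cfg$paths$vcf_b, annotation = an)
    cs <- intersect_callsets(cs, csb)
  }
  cs$geno <- missing_to_reference(cs$geno)
  traits <- if (!is.null(cfg$paths$traits)) read_traits(cfg$paths$traits)
            else trait_table(ped)
  traits <- ascertainment_weights(traits, ped)
  windows <- candidate_windows(read_bed(cfg$paths$gene_spans), pad_bp = th$pad_bp)
  v <- categorize(cs$variants, windows, known_rare_maf_max = th$known_rare_maf_max)
  gids <- intersect(rownames(cs$geno), ped$id[ped$genotyped])
  assoc <- list()
  for (cat in c("rare_private", "known_rare", "candidate_gene")) {
    sel <- v[[paste0("cat_", cat)]] & v$category == cat
    if (!any(sel)) next
    sc <- variant_association_scan(v[sel, ], cs$geno, traits, ped)
    sc$category <- cat
    assoc[[cat]] <- sc
  }
  assoc <- do.call(rbind, assoc)
  assoc$family_maf <- vapply(assoc$key, function(k)
    family_maf(cs$geno, k, gids), numeric(1))
  nominal <- unique(assoc$key[assoc$testable & !is.na(assoc$p_value) &
                                assoc$p_value < th$alpha])
  seg <- if (length(nominal)) segregation_scan(nominal, cs$geno, ped)
         else data.frame(key = character(0), family_id = character(0),
                         passes = logical(0), reasons = character(0))
  pass_keys <- seg$key[seg$passes]
  genes <- unique(stats::na.omit(v$gene[variant_key(v) %in% pass_keys]))
  dir.create(cfg$paths$outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(cfg$paths$outdir,
                     c("association.tsv", "segregation.tsv", "gene_list.txt"))
  names(paths) <- c("association", "segregation", "gene_list")
  on_err <- function(e) { unlink(paths); stop(e) }
  tryCatch({
    utils::write.table(assoc, paths["association"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(seg, paths["segregation"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    writeLines(genes, paths["gene_list"])
  }, error = on_err)
  invisible(list(genes = genes, association = assoc, segregation = seg,
                 paths = paths))
}

#' Run stage two: burden validation
#'
#' Builds per-gene allele-count tables for the deleterious and regulatory
#' classes — from a pre-aggregated counts TSV (`burden_counts` path) or
#' from case/control VCF+annotation pairs (`case_vcf`, `control_vcf`,
#' `cohort_annotation`) — runs the one-sided exact burden scan with
#' Bonferroni correction, and writes `burden_deleterious.tsv`,
#' `burden_regulatory.tsv` and a `manifest.yaml` echoing the
#' configuration, seed and package version. Rerunning with the same
#' config yields identical outputs.
#'
#' @param cfg a `run_config`.
#' @param genes nonempty character vector of genes to test (stage-one
#'   output).
#' @return invisibly, the `burden_scan` data frame plus written paths.
#' @export
run_stage2 <- function(cfg, genes) {
  if (length(genes) == 0) stop("stage2: empty gene list")
  if (is.null(cfg$paths$outdir)) stop("config error: missing 'outdir'")
  th <- cfg$thresholds
  set.seed(cfg$seed)
  if (!is.null(cfg$paths$burden_counts)) {
    require_paths(cfg, "burden_counts")
    tabs <- read_burden_counts(cfg$paths$burden_counts)
    tabs <- Filter(function(tb) tb$gene %in% genes, tabs)
  } else {
    require_paths(cfg, c("case_vcf", "control_vcf", "cohort_annotation"))
    an <- read_annotation(cfg$paths$cohort_annotation)
    cases <- read_vcf(cfg$paths$case_vcf, annotation = an)
    controls <- read_vcf(cfg$paths$control_vcf, annotation = an)
    cases$geno <- missing_to_reference(cases$geno)
    controls$geno <- missing_to_reference(controls$geno)
    tabs <- list()
    for (g in genes) for (vc in c("deleterious", "regulatory")) {
      tabs[[paste(g, vc, sep = ":")]] <-
        build_burden_table(g, vc, cases, controls, maf_max = th$burden_maf_max)
    }
  }
  if (!length(tabs)) stop("stage2: no burden tables for the requested genes")
  scan <- burden_scan(tabs, m = cfg$bonferroni_m)
  dir.create(cfg$paths$outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(cfg$paths$outdir,
                     c("burden_deleterious.tsv", "burden_regulatory.tsv",
                       "manifest.yaml"))
  names(paths) <- c("deleterious", "regulatory", "manifest")
  on_err <- function(e) { unlink(paths); stop(e) }
  tryCatch({
    for (vc in c("deleterious", "regulatory")) {
      part <- scan[scan$variant_class == vc, ]
      utils::write.table(part, paths[[vc]], sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    manifest <- list(
      config = list(paths = cfg$paths, thresholds = cfg$thresholds,
                    bonferroni_m = cfg$bonferroni_m),
      seed = cfg$seed, genes = as.list(genes),
      package_version = as.character(utils::packageVersion("famrisk")))
    yaml::write_yaml(manifest, paths["manifest"])
  }, error = on_err)
  invisible(list(scan = scan, paths = paths))
}
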