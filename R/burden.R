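#' One-sided Fisher exact test on a 2x2 allele-count table
#'
#' Exact hypergeometric tail probability for the table
#' `rbind(c(case_minor, case_major), c(control_minor, control_major))`,
#' conditioning on both margins. The upper tail on the case minor count
#' tests enrichment in cases, the lower tail tests depletion;
#' `direction = "observed"` picks the tail toward the sample effect.
#' Probabilities are computed from log-gamma factorials and summed over
#' the whole support (log-sum-exp), so tiny tails stay accurate. A zero
#' margin gives p = 1.
#'
#' @param case_minor,case_major,control_minor,control_major nonnegative
#'   integer counts.
#' @param direction `"observed"`, `"enrichment"` or `"depletion"`.
#' @return exact one-sided p-value in (0, 1].
#' @export
fisher_one_sided <- function(case_minor, case_major, control_minor,
                             control_major,
                             direction = c("observed", "enrichment",
                                           "depletion")) {
  direction <- match.arg(direction)
  cnt <- c(case_minor, case_major, control_minor, control_major)
  if (any(cnt < 0) || any(cnt != round(cnt)))
    stop("counts must be nonnegative integers")
  K <- case_minor + control_minor        # minor-allele margin
  N <- sum(cnt)                          # all alleles
  n1 <- case_minor + case_major          # case margin
  if (K == 0 || K == N || n1 == 0 || n1 == N) return(1)
  kmin <- max(0, n1 - (N - K))
  kmax <- min(n1, K)
  supp <- kmin:kmax
  logp <- lchoose(K, supp) + lchoose(N - K, n1 - supp) - lchoose(N, n1)
  tail_p <- function(sel) {
    lp <- logp[sel]
    mx <- max(lp)
    min(1, exp(mx) * sum(exp(lp - mx)))
  }
  if (direction == "observed") {
    direction <- if (case_minor >= n1 * K / N) "enrichment" else "depletion"
  }
  if (direction == "enrichment") tail_p(supp >= case_minor)
  else tail_p(supp <= case_minor)
}

#' Sample odds ratio of an allele-count table
#'
#' Cross-product ratio `(case_minor * control_major) /
#' (case_major * control_minor)`. A zero case minor count gives 0; a zero
#' control minor count with carriers in cases gives `Inf`; a table with no
#' minor alleles at all gives `NA`. Set `conditional = TRUE` for the
#' conditional maximum-likelihood odds ratio (the estimate reported by
#' [stats::fisher.test()]).
#'
#' @inheritParams fisher_one_sided
#' @param conditional use the conditional-MLE estimate instead of the
#'   sample cross-product ratio.
#' @return odds ratio in `[0, Inf]`.
#' @export
odds_ratio <- function(case_minor, case_major, control_minor, control_major,
                       conditional = FALSE) {
  if (conditional) {
    ft <- stats::fisher.test(matrix(c(case_minor, control_minor,
                                      case_major, control_major), 2, 2))
    return(unname(ft$estimate))
  }
  if (case_minor == 0 && control_minor == 0) return(NA_real_)
  if (case_minor == 0) return(0)
  if (control_minor == 0) return(Inf)
  (case_minor * control_major) / (case_major * control_minor)
}

burden_table_row <- function(gene, variant_class, case_minor, case_variants,
                             case_n, control_minor, control_variants,
                             control_n) {
  structure(list(
    gene = gene, variant_class = variant_class,
    case_minor = case_minor, case_variants = case_variants, case_n = case_n,
    control_minor = control_minor, control_variants = control_variants,
    control_n = control_n
  ), class = "burden_table")
}

#' Derived major-allele counts of a burden table
#'
#' The major-allele denominator is twice the cohort size times the number
#' of qualifying variants observed in that cohort, minus the minor count
#' (each qualifying variant contributes `2 n` allele slots). Majors are
#' always recomputed from the stored counts, never stored.
#'
#' @param tab a `burden_table`.
#' @return named vector `c(case_major, control_major)`.
#' @export
burden_majors <- function(tab) {
  c(case_major = 2 * tab$case_n * tab$case_variants - tab$case_minor,
    control_major = 2 * tab$control_n * tab$control_variants - tab$control_minor)
}

#' @export
print.burden_table <- function(x, ...) {
  mj <- burden_majors(x)
  cat(sprintf("%s [%s]: cases %d minor / %d major (%d variants, n=%d); controls %d / %d (%d variants, n=%d)\n",
              x$gene, x$variant_class, x$case_minor, mj["case_major"],
              x$case_variants, x$case_n, x$control_minor,
              mj["control_major"], x$control_variants, x$control_n))
  invisible(x)
}

#' Build a per-gene allele-count burden table from cohort genotypes
#'
#' Qualifying variants are those annotated to `gene`, passing the class
#' predicate (`"deleterious"`: nonsynonymous or stop variants called
#' deleterious by both SIFT and PolyPhen-2; `"regulatory"`: RegulomeDB
#' rank at most 2) and rare (`MAF < maf_max`, computed on the combined
#' cohorts by default, or taken from the annotation's population MAF).
#' A variant qualifies *in a cohort* only if observed there (minor count
#' >= 1); counts are summed over each cohort's qualifying variants, and
#' major counts are derived by [burden_majors()].
#'
#' @param gene gene symbol.
#' @param variant_class `"deleterious"` or `"regulatory"`.
#' @param cases,controls callsets (`list(variants, geno)`) with annotation
#'   columns populated.
#' @param maf_max rarity ceiling (default 0.05).
#' @param maf_source `"combined"` (cohort-combined allele frequency) or
#'   `"pop"` (the annotation's reference population MAF).
#' @return a `burden_table`.
#' @export
build_burden_table <- function(gene, variant_class = c("deleterious",
                                                       "regulatory"),
                               cases, controls, maf_max = 0.05,
                               maf_source = c("combined", "pop")) {
  variant_class <- match.arg(variant_class)
  maf_source <- match.arg(maf_source)
  va <- pad_annotation(cases$variants)
  vb <- pad_annotation(controls$variants)
  if (!gene %in% c(va$gene, vb$gene))
    stop("gene absent from annotation: ", gene)
  pick <- function(v) {
    cls <- if (variant_class == "deleterious")
      classify_deleterious(v, mode = "burden") else classify_regulatory(v)
    variant_key(v)[!is.na(v$gene) & v$gene == gene & cls]
  }
  keys <- union(pick(va), pick(vb))
  count_in <- function(callset, key) {
    kk <- variant_key(callset$variants)
    if (!key %in% kk) return(0)
    sum(callset$geno[, match(key, kk)], na.rm = TRUE)
  }
  n_case <- nrow(cases$geno)
  n_ctrl <- nrow(controls$geno)
  keep <- vapply(keys, function(k) {
    ca <- count_in(cases, k); cb <- count_in(controls, k)
    maf <- if (maf_source == "combined") {
      (ca + cb) / (2 * (n_case + n_ctrl))
    } else {
      v <- rbind(va[match(k, variant_key(va)), , drop = FALSE],
                 vb[match(k, variant_key(vb)), , drop = FALSE])
      m <- v$pop_maf[!is.na(v$pop_maf)]
      if (length(m)) m[1] else 0  # unseen in the reference: rare
    }
    maf < maf_max
  }, logical(1))
  keys <- keys[keep]
  case_counts <- vapply(keys, count_in, numeric(1), callset = cases)
  ctrl_counts <- vapply(keys, count_in, numeric(1), callset = controls)
  burden_table_row(
    gene, variant_class,
    case_minor = sum(case_counts[case_counts >= 1]),
    case_variants = sum(case_counts >= 1),
    case_n = n_case,
    control_minor = sum(ctrl_counts[ctrl_counts >= 1]),
    control_variants = sum(ctrl_counts >= 1),
    control_n = n_ctrl
  )
}

#' Burden table from pre-aggregated counts
#'
#' @param gene gene symbol.
#' @param variant_class `"deleterious"` or `"regulatory"`.
#' @param case_minor,case_variants,case_n,control_minor,control_variants,control_n
#'   aggregated counts (minor alleles, qualifying variants, cohort size).
#' @return a `burden_table`.
#' @export
burden_table_from_counts <- function(gene, variant_class, case_minor,
                                     case_variants, case_n, control_minor,
                                     control_variants, control_n) {
  stopifnot(case_minor <= 2 * case_n * case_variants,
            control_minor <= 2 * control_n * control_variants)
  burden_table_row(gene, variant_class, case_minor, case_variants, case_n,
                   control_minor, control_variants, control_n)
}

#' Gene-level burden scan with Bonferroni correction
#'
#' Runs the one-sided exact test and odds ratio over a list of burden
#' tables. A table is testable when at least one cohort observed at least
#' one qualifying minor allele; all-zero tables are reported untested and
#' excluded from the Bonferroni multiplier. The multiplier `m` defaults to
#' the number of testable tables within each variant class, or can be
#' fixed.
#'
#' @param tables list of `burden_table` objects.
#' @param direction tail choice passed to [fisher_one_sided()].
#' @param m `"testable"` or a fixed integer multiplier.
#' @return data frame of class `burden_scan`: one row per table with
#'   counts, `odds_ratio`, `direction`, `p_value`, `q_value`, `testable`,
#'   sorted by class then p.
#' @export
burden_scan <- function(tables, direction = "observed", m = "testable") {
  rows <- lapply(tables, function(tb) {
    mj <- burden_majors(tb)
    testable <- (tb$case_minor + tb$control_minor) > 0 &&
      (tb$case_variants + tb$control_variants) > 0
    if (testable) {
      p <- fisher_one_sided(tb$case_minor, mj[["case_major"]],
                            tb$control_minor, mj[["control_major"]],
                            direction = direction)
      or <- odds_ratio(tb$case_minor, mj[["case_major"]],
                       tb$control_minor, mj[["control_major"]])
      case_f <- tb$case_minor / max(1, tb$case_minor + mj[["case_major"]])
      ctrl_f <- tb$control_minor / max(1, tb$control_minor + mj[["control_major"]])
      dir <- if (case_f >= ctrl_f) "enrichment" else "depletion"
    } else {
      p <- NA_real_; or <- NA_real_; dir <- NA_character_
    }
    data.frame(gene = tb$gene, variant_class = tb$variant_class,
               case_minor = tb$case_minor, case_variants = tb$case_variants,
               case_major = mj[["case_major"]],
               control_minor = tb$control_minor,
               control_variants = tb$control_variants,
               control_major = mj[["control_major"]],
               odds_ratio = or, direction = dir, p_value = p,
               testable = testable, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- NA_real_
  for (cl in unique(out$variant_class)) {
    sel <- out$variant_class == cl
    mm <- if (identical(m, "testable")) sum(out$testable[sel]) else as.integer(m)
    out$q_value[sel] <- ifelse(out$testable[sel],
                               pmin(1, mm * out$p_value[sel]), NA_real_)
  }
  out <- out[order(out$variant_class, !out$testable, out$p_value), ]
  rownames(out) <- NULL
  class(out) <- c("burden_scan", "data.frame")
  out
}

#' @export
print.burden_scan <- function(x, ...) {
  cat(sprintf("Burden scan: %d gene x class tables%s\n", nrow(x),
              if (is.null(x$testable)) ""
              else sprintf(" (%d testable)", sum(x$testable))))
  print.data.frame(x, digits = 3, ...)
  invisible(x)
}

#' Read / write pre-aggregated burden counts
#'
#' Tab-separated with header and one row per (gene, class, cohort):
#' columns `gene, class, cohort, minor, n_variants, n_samples` with cohort
#' in `{case, control}`. Counts round-trip exactly.
#'
#' @param path file path.
#' @return list of `burden_table` objects.
#' @export
read_burden_counts <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  for (cl in c("minor", "n_variants", "n_samples"))
    df[[cl]] <- as.numeric(df[[cl]])
  tabs <- list()
  for (gene in unique(df$gene)) for (cl in unique(df$class[df$gene == gene])) {
    ca <- df[df$gene == gene & df$class == cl & df$cohort == "case", ]
    co <- df[df$gene == gene & df$class == cl & df$cohort == "control", ]
    if (nrow(ca) != 1 || nrow(co) != 1)
      stop("burden counts need one case and one control row per gene/class: ",
           gene, "/", cl)
    tabs[[paste(gene, cl, sep = ":")]] <- burden_table_from_counts(
      gene, cl, ca$minor, ca$n_variants, ca$n_samples,
      co$minor, co$n_variants, co$n_samples)
  }
  tabs
}

#' @rdname read_burden_counts
#' @param tables list of `burden_table` objects.
#' @export
write_burden_counts <- function(tables, path) {
  rows <- lapply(tables, function(tb) {
    data.frame(gene = tb$gene, class = tb$variant_class,
               cohort = c("case", "control"),
               minor = c(tb$case_minor, tb$control_minor),
               n_variants = c(tb$case_variants, tb$control_variants),
               n_samples = c(tb$case_n, tb$control_n),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
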