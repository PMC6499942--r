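#' Measured-genotype association scan over prioritized variants
#'
#' For each variant and each requested cancer outcome, fits the matching
#' polygenic model without (null) and with (full) the additive minor-allele
#' dosage as a fixed effect, and tests the dosage by a likelihood-ratio
#' test: `Lambda = 2 (l_full - l_null)` clipped at 0, `p` from the upper
#' tail of chi-square with 1 df, and Bonferroni `q = min(1, m p)` with `m`
#' the number of testable variants in the scanned list (the prioritized
#' category list defines the correction burden). Quantitative outcomes
#' (onset ages, 0 for unaffected) are inverse-normalized before fitting;
#' binary outcomes use the liability-threshold model.
#'
#' Covariates are age, sex, their interaction, and the probit
#' ascertainment weight `w`. Samples with missing covariates or outcome
#' are dropped per outcome. Variants monomorphic across the used samples
#' are flagged non-testable and excluded from `m`.
#'
#' @param variants variant data frame.
#' @param geno dosage matrix (missing values resolved).
#' @param traits trait table with `w` populated.
#' @param ped the `famped` table (source of the kinship matrix).
#' @param outcomes subset of `c("age_onset_cancer", "age_onset_sarcoma",
#'   "any_cancer", "any_sarcoma")`.
#' @param covariates subset of `c("age", "sex", "age_sex", "w")` to include
#'   as fixed effects beside the intercept (default: all four).
#' @return data frame of class `assoc_scan`: one row per
#'   variant x outcome with `key`, `gene`, `outcome`, `lrt`, `p_value`,
#'   `q_value`, `testable`, `note`, sorted by p within outcome.
#' @export
variant_association_scan <- function(variants, geno, traits, ped,
                                     outcomes = c("age_onset_cancer",
                                                  "age_onset_sarcoma",
                                                  "any_cancer",
                                                  "any_sarcoma"),
                                     covariates = c("age", "sex",
                                                    "age_sex", "w")) {
  outcomes <- match.arg(outcomes, several.ok = TRUE)
  covariates <- match.arg(covariates, several.ok = TRUE)
  keys <- variant_key(variants)
  phi_all <- kinship(ped)
  res <- list()
  for (oc in outcomes) {
    binary <- oc %in% c("any_cancer", "any_sarcoma")
    ids <- intersect(traits$sample_id, rownames(geno))
    tr <- traits[match(ids, traits$sample_id), ]
    need <- intersect(unique(sub("age_sex", "age", covariates)),
                      c("age", "sex", "w"))
    if ("age_sex" %in% covariates) need <- union(need, c("age", "sex"))
    covar_ok <- (if (length(need)) stats::complete.cases(tr[, need, drop = FALSE])
                 else TRUE) & !is.na(tr[[oc]])
    ids <- ids[covar_ok]
    tr <- tr[covar_ok, ]
    note <- ""
    if (length(ids) < 3) {
      res[[oc]] <- data.frame(key = keys, gene = variants$gene, outcome = oc,
                              lrt = NA_real_, p_value = NA_real_,
                              q_value = NA_real_, testable = FALSE,
                              note = "too few phenotyped samples",
                              stringsAsFactors = FALSE)
      next
    }
    # covariates are standardized for numerical stability; the likelihood-
    # ratio test is invariant under this affine rescaling
    std <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x * 0
    age_s <- std(tr$age)
    cols <- list(age = age_s, sex = tr$sex, age_sex = age_s * tr$sex,
                 w = std(tr$w))
    X <- cbind(intercept = rep(1, nrow(tr)))
    for (cv in covariates) X <- cbind(X, cols[[cv]])
    colnames(X) <- c("intercept", covariates)
    phi <- phi_all[ids, ids]
    fam <- ped$fid[match(ids, ped$id)]
    g <- geno[ids, , drop = FALSE]
    if (binary) {
      y <- tr[[oc]]
      null_fit <- fit_liability(y, X, phi, fam)
      # full fits warm-start from the null solution (dosage effect at 0)
      warm <- if (isTRUE(null_fit$estimable) && null_fit$converged)
        c(null_fit$coefficients, 0, null_fit$h2) else NULL
      fitter <- function(dos) fit_liability(y, X, phi, fam, dosage = dos,
                                            start = warm)
    } else {
      yraw <- tr[[oc]]
      if (all(yraw == yraw[1])) {
        res[[oc]] <- data.frame(key = keys, gene = variants$gene, outcome = oc,
                                lrt = NA_real_, p_value = NA_real_,
                                q_value = NA_real_, testable = FALSE,
                                note = "outcome constant", stringsAsFactors = FALSE)
        next
      }
      y <- inverse_normal(yraw)
      null_fit <- fit_polygenic(y, X, phi)
      fitter <- function(dos) fit_polygenic(y, X, phi, dosage = dos)
    }
    if (binary && !null_fit$estimable) {
      res[[oc]] <- data.frame(key = keys, gene = variants$gene, outcome = oc,
                              lrt = NA_real_, p_value = NA_real_,
                              q_value = NA_real_, testable = FALSE,
                              note = "outcome non-estimable",
                              stringsAsFactors = FALSE)
      next
    }
    lrt <- p <- rep(NA_real_, length(keys))
    testable <- rep(FALSE, length(keys))
    note_v <- rep("", length(keys))
    for (k in seq_along(keys)) {
      dos <- g[, keys[k]]
      if (anyNA(dos)) stop("scan requires complete genotypes (apply missing_to_reference)")
      if (length(unique(dos)) < 2) {
        note_v[k] <- "monomorphic"
        next
      }
      full_fit <- fitter(dos)
      if (binary && (!full_fit$estimable || !is.finite(full_fit$loglik))) {
        note_v[k] <- "full model non-estimable"
        next
      }
      lrt[k] <- max(0, 2 * (full_fit$loglik - null_fit$loglik))
      p[k] <- stats::pchisq(lrt[k], df = 1, lower.tail = FALSE)
      testable[k] <- TRUE
    }
    m <- sum(testable)
    q <- ifelse(testable, pmin(1, m * p), NA_real_)
    res[[oc]] <- data.frame(key = keys, gene = variants$gene, outcome = oc,
                            lrt = lrt, p_value = p, q_value = q,
                            testable = testable, note = note_v,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out <- out[order(out$outcome, !out$testable, out$p_value), ]
  rownames(out) <- NULL
  class(out) <- c("assoc_scan", "data.frame")
  out
}

#' @export
print.assoc_scan <- function(x, ...) {
  cat(sprintf("Association scan: %d variant x outcome tests%s\n", nrow(x),
              if (is.null(x$testable)) ""
              else sprintf(" (%d testable)", sum(x$testable))))
  print.data.frame(x, digits = 4, ...)
  invisible(x)
}
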