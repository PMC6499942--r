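#' Construct a pedigree table
#'
#' A pedigree is stored as a data frame with one row per individual and a
#' `famped` class. Several families may share one table; `fid` keeps them
#' apart and individual ids must be unique across the whole table (the
#' kinship matrix spans all families, with zero kinship between them).
#'
#' @param fid family identifier (character, recycled).
#' @param id individual identifier, unique across the table.
#' @param father,mother parental ids, `NA` for founders. An individual must
#'   have either both parents or neither.
#' @param sex one of `"male"`, `"female"`, `"unknown"`.
#' @param affected_cancer,affected_sarcoma affection status, one of
#'   `"yes"`, `"no"`, `"unknown"`. A sarcoma diagnosis implies a cancer
#'   diagnosis.
#' @param age current age in years (`NA` allowed).
#' @param onset_age age at cancer onset in years; must be `NA` for
#'   individuals with `affected_cancer = "no"`.
#' @param proband logical; exactly one proband per family in study mode.
#' @param genotyped logical; individuals without DNA stay in the graph (they
#'   contribute to kinship and the phenotype model) but are excluded from
#'   genotype-dependent stages.
#' @return a `famped` data frame.
#' @export
pedigree <- function(fid, id, father = NA_character_, mother = NA_character_,
                     sex = "unknown", affected_cancer = "unknown",
                     affected_sarcoma = "unknown", age = NA_real_,
                     onset_age = NA_real_, proband = FALSE,
                     genotyped = TRUE) {
  n <- length(id)
  ped <- data.frame(
    fid = rep_len(as.character(fid), n),
    id = as.character(id),
    father = rep_len(as.character(father), n),
    mother = rep_len(as.character(mother), n),
    sex = rep_len(as.character(sex), n),
    affected_cancer = rep_len(as.character(affected_cancer), n),
    affected_sarcoma = rep_len(as.character(affected_sarcoma), n),
    age = rep_len(as.numeric(age), n),
    onset_age = rep_len(as.numeric(onset_age), n),
    proband = rep_len(as.logical(proband), n),
    genotyped = rep_len(as.logical(genotyped), n),
    stringsAsFactors = FALSE
  )
  class(ped) <- c("famped", "data.frame")
  ped
}

#' @export
print.famped <- function(x, ...) {
  cat(sprintf("Pedigree table: %d individuals in %d famil%s\n",
              nrow(x), length(unique(x$fid)),
              if (length(unique(x$fid)) == 1L) "y" else "ies"))
  cat(sprintf("  affected (cancer): %d   genotyped: %d   probands: %d\n",
              sum(x$affected_cancer == "yes"), sum(x$genotyped),
              sum(x$proband)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Combine pedigree tables
#' @param ... `famped` tables.
#' @param deparse.level unused.
#' @export
rbind.famped <- function(..., deparse.level = 1) {
  out <- do.call(rbind.data.frame, lapply(list(...), as.data.frame))
  class(out) <- c("famped", "data.frame")
  rownames(out) <- NULL
  out
}

sex_levels <- c("male", "female", "unknown")
aff_levels <- c("yes", "no", "unknown")

#' Validate a pedigree table
#'
#' Checks the structural invariants of the family graph. Violations are
#' returned as data, not raised: each element names the individual (or
#' family) and the rule broken.
#'
#' @param ped a `famped` table.
#' @param study_mode if `TRUE`, additionally require exactly one proband per
#'   family (the ascertainment design assumes proband-based sampling).
#' @return character vector of violation descriptions; empty iff valid.
#' @export
validate_pedigree <- function(ped, study_mode = TRUE) {
  v <- character(0)
  bad <- function(fmt, ...) sprintf(fmt, ...)
  if (anyDuplicated(ped$id)) {
    v <- c(v, bad("duplicate individual id(s): %s",
                  paste(unique(ped$id[duplicated(ped$id)]), collapse = ", ")))
  }
  for (k in seq_len(nrow(ped))) {
    r <- ped[k, ]
    if (!r$sex %in% sex_levels)
      v <- c(v, bad("%s: invalid sex '%s'", r$id, r$sex))
    if (!r$affected_cancer %in% aff_levels)
      v <- c(v, bad("%s: invalid cancer status '%s'", r$id, r$affected_cancer))
    if (!r$affected_sarcoma %in% aff_levels)
      v <- c(v, bad("%s: invalid sarcoma status '%s'", r$id, r$affected_sarcoma))
    if (is.na(r$father) != is.na(r$mother))
      v <- c(v, bad("%s: has exactly one parent id (needs both or neither)", r$id))
    if (identical(r$affected_sarcoma, "yes") && !identical(r$affected_cancer, "yes"))
      v <- c(v, bad("%s: sarcoma-affected but not cancer-affected", r$id))
    if (identical(r$affected_cancer, "no") && !is.na(r$onset_age))
      v <- c(v, bad("%s: onset age set for cancer-unaffected individual", r$id))
    if (!is.na(r$age) && r$age < 0)
      v <- c(v, bad("%s: negative age", r$id))
    if (!is.na(r$onset_age) && r$onset_age < 0)
      v <- c(v, bad("%s: negative onset age", r$id))
    for (side in c("father", "mother")) {
      pid <- r[[side]]
      if (is.na(pid)) next
      hit <- which(ped$id == pid & ped$fid == r$fid)
      if (length(hit) == 0L) {
        v <- c(v, bad("%s: %s id '%s' not found in family %s", r$id, side, pid, r$fid))
      } else {
        want <- if (side == "father") "male" else "female"
        psex <- ped$sex[hit[1]]
        if (!psex %in% c(want, "unknown"))
          v <- c(v, bad("%s: %s '%s' has sex '%s'", r$id, side, pid, psex))
      }
    }
  }
  cyc <- topo_order(ped, quiet = TRUE)
  if (is.null(cyc))
    v <- c(v, "parentage graph contains a cycle")
  if (study_mode) {
    np <- tapply(ped$proband, ped$fid, sum)
    for (f in names(np)[np != 1L])
      v <- c(v, bad("family %s: %d probands (study mode requires exactly 1)", f, np[[f]]))
  }
  v
}

# Topological order of row indices (parents before children); NULL on cycle.
topo_order <- function(ped, quiet = FALSE) {
  n <- nrow(ped)
  fa <- match(ped$father, ped$id)
  mo <- match(ped$mother, ped$id)
  placed <- rep(FALSE, n)
  parent_ok <- function(pid, pidx) {
    ifelse(is.na(pid), TRUE,                   # founder slot
           ifelse(is.na(pidx), FALSE,          # unresolved id: never ready
                  placed[ifelse(is.na(pidx), 1L, pidx)]))
  }
  ord <- integer(0)
  repeat {
    ready <- !placed & parent_ok(ped$father, fa) & parent_ok(ped$mother, mo)
    if (!any(ready)) break
    ord <- c(ord, which(ready))
    placed[ready] <- TRUE
  }
  if (length(ord) < n) {
    unresolved <- (!is.na(ped$father) & is.na(fa)) | (!is.na(ped$mother) & is.na(mo))
    if (any(unresolved & !placed)) {
      if (quiet) return(NULL)
      stop("unresolved parent id(s) for: ",
           paste(ped$id[unresolved & !placed], collapse = ", "))
    }
    if (quiet) return(NULL)
    stop("parentage graph contains a cycle involving: ",
         paste(ped$id[!placed], collapse = ", "))
  }
  ord
}

#' Kinship matrix of a pedigree table
#'
#' Computes kinship coefficients by the standard recursion: founders are
#' pairwise unrelated, phi(i,j) = (phi(father_i, j) + phi(mother_i, j)) / 2
#' for a non-founder i processed after its parents, and
#' phi(i,i) = (1 + phi(father_i, mother_i)) / 2. Members of different
#' families have kinship zero. Sex plays no role.
#'
#' @param ped a `famped` table (must validate, probands aside).
#' @param mz_twins optional list of length-2 character vectors naming
#'   monozygotic twin pairs; their pairwise kinship is set to the self
#'   kinship phi(i,i). Dizygotic twins need no flag - they are ordinary full
#'   siblings.
#' @return symmetric matrix of kinship coefficients with ids as dimnames.
#'   Twice this matrix scales the additive genetic covariance.
#' @export
kinship <- function(ped, mz_twins = NULL) {
  ord <- topo_order(ped)
  n <- nrow(ped)
  fa <- match(ped$father, ped$id)
  mo <- match(ped$mother, ped$id)
  phi <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  seen <- integer(0)
  for (i in ord) {
    if (is.na(fa[i])) {
      phi[i, i] <- 0.5
    } else {
      phi[i, i] <- 0.5 * (1 + phi[fa[i], mo[i]])
      if (length(seen)) {
        vals <- 0.5 * (phi[fa[i], seen] + phi[mo[i], seen])
        phi[i, seen] <- vals
        phi[seen, i] <- vals
      }
    }
    seen <- c(seen, i)
  }
  if (!is.null(mz_twins)) {
    for (pair in mz_twins) {
      a <- match(pair[1], ped$id); b <- match(pair[2], ped$id)
      if (is.na(a) || is.na(b)) stop("mz twin id not in pedigree")
      phi[a, b] <- phi[b, a] <- phi[a, a]
    }
  }
  phi
}

#' Monte-Carlo kinship by gene dropping
#'
#' Drops uniquely labelled founder alleles through the pedigree under
#' Mendelian transmission and estimates phi(i,j) as the probability that
#' one allele sampled from i and one from j are identical by descent
#' (averaged over the four allele comparisons). Used as an independent
#' check of [kinship()].
#'
#' @param ped a `famped` table.
#' @param n_drops number of independent drops.
#' @return list with `phi` (estimate matrix) and `se` (elementwise Monte
#'   Carlo standard errors).
#' @export
kinship_gene_drop <- function(ped, n_drops = 20000) {
  ord <- topo_order(ped)
  n <- nrow(ped)
  fa <- match(ped$father, ped$id)
  mo <- match(ped$mother, ped$id)
  a1 <- matrix(0L, n_drops, n)
  a2 <- matrix(0L, n_drops, n)
  lab <- 0L
  for (i in ord) {
    if (is.na(fa[i])) {
      a1[, i] <- lab + 1L
      a2[, i] <- lab + 2L
      lab <- lab + 2L
    } else {
      pick <- stats::runif(n_drops) < 0.5
      a1[, i] <- ifelse(pick, a1[, fa[i]], a2[, fa[i]])
      pick <- stats::runif(n_drops) < 0.5
      a2[, i] <- ifelse(pick, a1[, mo[i]], a2[, mo[i]])
    }
  }
  phi <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  se <- phi
  for (i in seq_len(n)) for (j in seq_len(i)) {
    sh <- ((a1[, i] == a1[, j]) + (a1[, i] == a2[, j]) +
           (a2[, i] == a1[, j]) + (a2[, i] == a2[, j])) / 4
    phi[i, j] <- phi[j, i] <- mean(sh)
    se[i, j] <- se[j, i] <- stats::sd(sh) / sqrt(n_drops)
  }
  list(phi = phi, se = se)
}
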