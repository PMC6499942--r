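# Jeffreys-penalized (Firth-type) probit regression.
#
# Proband-ascertained family data routinely separate (every proband is
# affected by construction), where plain ML probit diverges. Maximizing the
# likelihood penalized by half the log determinant of the Fisher
# information keeps the estimates finite and shrinks the small-sample bias.
br_probit <- function(y, X) {
  X <- as.matrix(X)
  p <- ncol(X)
  negpen <- function(beta) {
    eta <- drop(X %*% beta)
    pr <- pmin(pmax(stats::pnorm(eta), 1e-12), 1 - 1e-12)
    ll <- sum(y * log(pr) + (1 - y) * log(1 - pr))
    phi <- stats::dnorm(eta)
    wts <- phi^2 / (pr * (1 - pr))
    info <- crossprod(X * sqrt(wts))
    ld <- determinant(info, logarithm = TRUE)
    if (ld$sign <= 0) return(1e10)
    -(ll + 0.5 * as.numeric(ld$modulus))
  }
  fit <- stats::optim(rep(0, p), negpen, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-10))
  beta <- fit$par
  list(coef = beta, eta = drop(X %*% beta), converged = fit$convergence == 0)
}

#' Probit ascertainment weights
#'
#' Families enter the study through an affected proband, which inflates
#' the apparent familial risk; a probit score of affection status is used
#' downstream as a fixed-effect covariate to absorb that ascertainment
#' bias. The score is the fitted linear predictor of a bias-reduced
#' (Jeffreys-penalized) probit regression of cancer status on the proband
#' flag and, optionally, relatedness to the proband (twice the kinship
#' coefficient with the family's proband).
#'
#' If affection status does not vary (all affected or all unaffected),
#' weights are set to 0 with a warning. Individuals with unknown status
#' get weight 0.
#'
#' @param traits trait data frame (see [trait_table()]); the returned copy
#'   has its `w` column populated.
#' @param ped the `famped` table the traits came from (must carry one
#'   proband per family).
#' @param design `"proband_relatedness"` (default) or `"proband_only"`.
#' @return `traits` with `w` filled in.
#' @export
ascertainment_weights <- function(traits, ped,
                                  design = c("proband_relatedness",
                                             "proband_only")) {
  design <- match.arg(design)
  idx <- match(traits$sample_id, ped$id)
  if (anyNA(idx)) stop("trait sample(s) not in pedigree: ",
                       paste(traits$sample_id[is.na(idx)], collapse = ", "))
  y <- traits$any_cancer
  usable <- !is.na(y)
  traits$w <- 0
  if (!any(usable) || length(unique(y[usable])) < 2) {
    warning("affection status does not vary; ascertainment weights set to 0")
    return(traits)
  }
  pro <- as.numeric(ped$proband[idx])
  X <- cbind(intercept = 1, proband = pro)
  if (design == "proband_relatedness") {
    phi <- kinship(ped)
    rel <- numeric(length(idx))
    for (k in seq_along(idx)) {
      fam <- ped$fid[idx[k]]
      pid <- ped$id[ped$fid == fam & ped$proband]
      rel[k] <- if (length(pid)) 2 * phi[ped$id[idx[k]], pid[1]] else 0
    }
    X <- cbind(X, relatedness = rel)
  }
  fit <- br_probit(y[usable], X[usable, , drop = FALSE])
  traits$w[usable] <- fit$eta
  traits
}
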