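#' Fit a liability-threshold model with a polygenic variance component
#'
#' Binary affection is modelled through a latent Gaussian liability
#' `L ~ MVN(X beta, 2 Phi h2 + I (1 - h2))`: an individual is affected iff
#' their liability exceeds 0 (the population threshold is absorbed into the
#' intercept, so the mean component is a probit regression). The total
#' liability variance is constrained to 1, making `h2` the narrow-sense
#' liability heritability. Each pedigree contributes the multivariate
#' normal rectangle probability of its observed affection pattern
#' (`(0, Inf)` for affected, `(-Inf, 0)` for unaffected members);
#' rectangle probabilities are evaluated by deterministic quasi-Monte
#' Carlo to absolute tolerance 1e-4.
#'
#' Optimization is bounded quasi-Newton (L-BFGS-B) over `(beta, h2)` with
#' three deterministic restarts. With no variation in status the model is
#' flagged non-estimable; pedigrees with more than 25 phenotyped members
#' exceed the integration-dimension cap and raise an error.
#'
#' @param status 0/1 affection vector.
#' @param X fixed-effect design matrix (include the intercept).
#' @param phi kinship matrix over the same samples.
#' @param fam family id per sample; liability is correlated only within a
#'   family, so the likelihood factorizes over families.
#' @param dosage optional additive genotype dosage appended to `X`.
#' @param h2_fixed fix the heritability instead of estimating it (also
#'   used automatically, at 0, when all samples are mutually unrelated and
#'   `h2` is unidentifiable).
#' @param start optional warm-start parameter vector `c(beta, h2)`
#'   (without the `h2` entry when `h2_fixed` is given); when supplied it
#'   replaces the deterministic restarts unless `n_restarts > 1`.
#' @param n_restarts number of deterministic starts (default 3).
#' @return object of class `liability_fit` with elements `coefficients`,
#'   `h2`, `sigma2_g` (= `h2`), `sigma2_e` (= `1 - h2`), `loglik`,
#'   `converged`, `estimable`, `n_used`.
#' @export
fit_liability <- function(status, X, phi, fam, dosage = NULL,
                          h2_fixed = NULL, start = NULL, n_restarts = 3L) {
  X <- as.matrix(X)
  if (!is.null(dosage)) X <- cbind(X, dosage = dosage)
  n <- length(status)
  stopifnot(nrow(X) == n, nrow(phi) == n, length(fam) == n)
  stopifnot(all(status %in% c(0, 1)))
  fams <- split(seq_len(n), fam)
  if (any(lengths(fams) > 25L))
    stop("pedigree with more than 25 phenotyped members: integration dimension cap")
  out_skeleton <- function(estimable, cf = rep(NA_real_, ncol(X)), h2 = NA_real_,
                           ll = NA_real_, conv = FALSE) {
    names(cf) <- colnames(X)
    structure(list(coefficients = cf, h2 = h2, sigma2_g = h2,
                   sigma2_e = 1 - h2, loglik = ll, converged = conv,
                   estimable = estimable, n_used = n),
              class = "liability_fit")
  }
  if (length(unique(status)) < 2) return(out_skeleton(FALSE))

  A <- 2 * phi
  off <- A
  diag(off) <- 0
  unrelated <- all(abs(off) < 1e-12)
  if (unrelated && is.null(h2_fixed)) h2_fixed <- 0

  p <- ncol(X)
  # precompute per-family blocks once; negll only rescales them
  blocks <- lapply(fams, function(ix) list(
    ix = ix,
    A = A[ix, ix, drop = FALSE],
    lo = ifelse(status[ix] == 1, 0, -Inf),
    hi = ifelse(status[ix] == 1, Inf, 0)
  ))
  negll <- function(par) {
    beta <- par[seq_len(p)]
    h2 <- if (is.null(h2_fixed)) par[p + 1L] else h2_fixed
    eta <- drop(X %*% beta)
    ll <- 0
    for (b in blocks) {
      k <- length(b$ix)
      if (k == 1L || h2 == 0) {
        pr <- stats::pnorm(eta[b$ix])
        pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
        ll <- ll + sum(ifelse(status[b$ix] == 1, log(pr), log(1 - pr)))
      } else {
        S <- h2 * b$A + diag(1 - h2, k)
        pf <- pmvn_rect(b$lo, b$hi, eta[b$ix], S)
        ll <- ll + log(max(pf, 1e-300))
      }
    }
    -ll
  }

  npar <- p + as.integer(is.null(h2_fixed))
  lower <- c(rep(-20, p), if (is.null(h2_fixed)) 0)
  upper <- c(rep(20, p), if (is.null(h2_fixed)) 0.99)
  if (!is.null(start)) {
    stopifnot(length(start) == npar)
    starts <- list(pmin(pmax(start, lower), upper))
  } else {
    starts <- list(rep(0, npar))
    if (is.null(h2_fixed)) {
      starts[[1]][npar] <- 0.3
      starts[[2]] <- c(rep(0, p), 0.7)
      starts[[3]] <- c(stats::qnorm(mean(status)), rep(0, p - 1), 0.1)
    } else {
      starts[[2]] <- rep(0.1, npar)
      starts[[3]] <- c(stats::qnorm(mean(status)), rep(0, p - 1))
    }
    starts <- starts[seq_len(min(n_restarts, length(starts)))]
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, negll, method = "L-BFGS-B", lower = lower,
                   upper = upper,
                   control = list(maxit = 200, factr = 1e9)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) return(out_skeleton(TRUE, conv = FALSE))
  beta <- best$par[seq_len(p)]
  h2 <- if (is.null(h2_fixed)) best$par[p + 1L] else h2_fixed
  names(beta) <- colnames(X)
  out <- out_skeleton(TRUE, cf = beta, h2 = h2, ll = -best$value,
                      conv = best$convergence == 0)
  out$coefficients[] <- beta
  out
}

#' @export
print.liability_fit <- function(x, ...) {
  cat("Liability-threshold polygenic fit\n")
  if (!x$estimable) {
    cat("  non-estimable (no variation in affection status)\n")
    return(invisible(x))
  }
  cat(sprintf("  n = %d, logLik = %.4f, converged = %s\n",
              x$n_used, x$loglik, x$converged))
  cat(sprintf("  liability h2 = %.3f\n", x$h2))
  cat("  fixed effects (probit scale):\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.liability_fit <- function(object, ...) object$coefficients

#' @export
logLik.liability_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients) + 1,
            nobs = object$n_used, class = "logLik")
}

#' @export
summary.liability_fit <- function(object, ...) {
  if (!object$estimable) {
    cat("Liability model: non-estimable (no variation in status)\n")
  } else {
    cat(sprintf("Liability model: n = %d, h2 = %.3f, logLik = %.4f\n",
                object$n_used, object$h2, object$loglik))
  }
  invisible(object)
}
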