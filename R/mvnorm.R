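# Deterministic multivariate-normal rectangle probabilities.
#
# The liability likelihood needs P(lower < L < upper) for L ~ MVN(mu, Sigma)
# over orthant-type rectangles, evaluated thousands of times inside an
# optimizer. Computation goes through the Genz quasi-Monte-Carlo algorithm
# (mvtnorm::pmvnorm) with absolute tolerance 1e-4; the RNG state is pinned
# to a fixed internal seed around each call and restored afterwards, so
# repeated evaluations are bit-identical and the likelihood surface stays
# deterministic for the optimizer. One- and zero-correlation cases short-
# circuit to exact univariate products.

pmvn_rect <- function(lower, upper, mean, sigma, abseps = 1e-4,
                      maxpts = 25000L) {
  d <- length(mean)
  if (d == 1L) {
    s <- sqrt(sigma[1, 1])
    return(stats::pnorm(upper, mean, s) - stats::pnorm(lower, mean, s))
  }
  off <- sigma
  diag(off) <- 0
  if (all(off == 0)) {  # independent case: product of univariate terms
    s <- sqrt(diag(sigma))
    return(prod(stats::pnorm(upper, mean, s) - stats::pnorm(lower, mean, s)))
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(271828L)
  p <- mvtnorm::pmvnorm(lower = lower, upper = upper, mean = mean,
                        sigma = sigma,
                        algorithm = mvtnorm::GenzBretz(abseps = abseps,
                                                       maxpts = maxpts))
  max(as.numeric(p), 0)
}
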