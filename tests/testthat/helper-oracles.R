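# Shared fixtures and independent oracle implementations used across tests.

# --- pedigree builders ------------------------------------------------------

trio <- function(fid = "t") {
  pedigree(fid = fid,
           id = paste0(fid, c("-f", "-m", "-c")),
           father = c(NA, NA, paste0(fid, "-f")),
           mother = c(NA, NA, paste0(fid, "-m")),
           sex = c("male", "female", "female"),
           proband = c(FALSE, FALSE, TRUE))
}

nuclear_family <- function(fid = "n", n_kids = 2) {
  kids <- paste0(fid, "-c", seq_len(n_kids))
  pedigree(fid = fid,
           id = c(paste0(fid, "-f"), paste0(fid, "-m"), kids),
           father = c(NA, NA, rep(paste0(fid, "-f"), n_kids)),
           mother = c(NA, NA, rep(paste0(fid, "-m"), n_kids)),
           sex = c("male", "female", rep("unknown", n_kids)),
           proband = c(FALSE, FALSE, seq_len(n_kids) == 1))
}

# Random multigenerational pedigree of at most max_members members.
random_test_pedigree <- function(fid, max_members = 10) {
  famrisk:::random_family_structure(fid, sample(4:max_members, 1))
}

# --- burden oracle ----------------------------------------------------------

# One-sided Fisher p by direct enumeration over every table sharing the
# margins, point probabilities from products of binomial coefficients.
enum_fisher <- function(case_minor, case_major, control_minor, control_major,
                        upper = TRUE) {
  K <- case_minor + control_minor
  N <- case_minor + case_major + control_minor + control_major
  n1 <- case_minor + case_major
  if (K == 0 || K == N || n1 == 0 || n1 == N) return(1)
  supp <- max(0, n1 - (N - K)):min(n1, K)
  pmf <- choose(K, supp) * choose(N - K, n1 - supp) / choose(N, n1)
  sel <- if (upper) supp >= case_minor else supp <= case_minor
  min(1, sum(pmf[sel]))
}

# --- categorization oracle --------------------------------------------------

# Re-statement of the three category rules, one variant at a time.
brute_categorize <- function(rsid, pop_maf, chrom, pos, windows, maf_max) {
  rare_private <- is.na(rsid)
  known_rare <- !is.na(rsid) && !is.na(pop_maf) && pop_maf <= maf_max
  candidate <- FALSE
  if (!is.null(windows)) {
    for (k in seq_len(nrow(windows))) {
      if (chrom == windows$chrom[k] && pos >= windows$start[k] &&
          pos <= windows$end[k]) candidate <- TRUE
    }
  }
  primary <- if (rare_private) "rare_private" else if (known_rare) "known_rare"
    else if (candidate) "candidate_gene" else "none"
  list(rare_private = rare_private, known_rare = known_rare,
       candidate_gene = candidate, primary = primary)
}

# --- segregation oracle -----------------------------------------------------

# Independent truth-table checker over explicit carrier/affection vectors.
brute_segregation <- function(carrier, affected, fam) {
  reasons <- character(0)
  family_id <- NA_character_
  if (!any(carrier)) {
    reasons <- "no_carriers"
  } else {
    cf <- unique(fam[carrier])
    if (length(cf) > 1) reasons <- c(reasons, "not_single_family")
    else family_id <- cf
    if (any(carrier & !affected)) reasons <- c(reasons, "unaffected_carrier")
    if (length(cf) == 1 && any(!carrier & affected & fam == cf))
      reasons <- c(reasons, "affected_noncarrier")
  }
  list(passes = length(reasons) == 0, reasons = reasons,
       family_id = family_id)
}

# --- dense Gaussian likelihood oracle ---------------------------------------

# Direct dense-matrix evaluation of the polygenic Gaussian log-likelihood.
dense_gaussian_loglik <- function(y, X, phi, beta, sigma2_g, sigma2_e) {
  Sigma <- 2 * phi * sigma2_g + diag(sigma2_e, length(y))
  r <- y - drop(as.matrix(X) %*% beta)
  -0.5 * (determinant(Sigma)$modulus + sum(r * solve(Sigma, r)) +
            length(y) * log(2 * pi))
}

# --- bivariate normal rectangle oracle --------------------------------------

# P(l1 < X1 < u1, l2 < X2 < u2) for standardized bivariate normal with
# correlation rho, by 1-D quadrature over the conditional distribution.
biv_rect_quad <- function(l, u, mean, sigma) {
  s1 <- sqrt(sigma[1, 1]); s2 <- sqrt(sigma[2, 2])
  rho <- sigma[1, 2] / (s1 * s2)
  f <- function(x) {
    cm <- mean[2] + rho * s2 / s1 * (x - mean[1])
    cs <- s2 * sqrt(1 - rho^2)
    stats::dnorm(x, mean[1], s1) *
      (stats::pnorm(u[2], cm, cs) - stats::pnorm(l[2], cm, cs))
  }
  stats::integrate(f, max(l[1], mean[1] - 10 * s1),
                   min(u[1], mean[1] + 10 * s1), rel.tol = 1e-10)$value
}
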