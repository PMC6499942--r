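test_that("inverse normal scores follow the Blom formula and preserve ranks", {
  z <- inverse_normal(c(5, 2, 9))
  expect_equal(z[1], 0)                       # middle value -> 0 by symmetry
  expect_equal(z[2], qnorm(0.625 / 3.25))     # (1 - 3/8) / (3 - 3/4 + 1)
  expect_equal(z[3], -qnorm(0.625 / 3.25))
  set.seed(4)
  x <- rnorm(50)
  expect_identical(order(inverse_normal(x)), order(x))
  # averaged ranks for ties: equal inputs get equal scores
  zt <- inverse_normal(c(0, 0, 0, 7, 9))
  expect_true(all(zt[1:3] == zt[1]))
  expect_error(inverse_normal(rep(1, 5)), "identical")
  expect_error(inverse_normal(3), "at least 2")
})

test_that("MVN rectangle probabilities match closed forms and quadrature", {
  # univariate and independent cases are exact
  expect_equal(famrisk:::pmvn_rect(-Inf, 0.7, 0.2, matrix(1.3, 1, 1)),
               pnorm(0.7, 0.2, sqrt(1.3)))
  S <- diag(c(1, 2, 0.5))
  expect_equal(famrisk:::pmvn_rect(c(-Inf, 0, -1), c(0, Inf, 1), c(0, 0.3, 0), S),
               prod(pnorm(0) ,
                    pnorm(0.3 / sqrt(2)),
                    pnorm(1, 0, sqrt(0.5)) - pnorm(-1, 0, sqrt(0.5))))
  # correlated bivariate against a 1-D quadrature oracle
  S2 <- matrix(c(1, 0.6, 0.6, 1.4), 2, 2)
  got <- famrisk:::pmvn_rect(c(0, -Inf), c(Inf, 0), c(0.2, -0.1), S2)
  want <- biv_rect_quad(c(0, -Inf), c(Inf, 0), c(0.2, -0.1), S2)
  expect_equal(got, want, tolerance = 2e-4)
  # deterministic: repeated calls agree exactly
  expect_identical(got, famrisk:::pmvn_rect(c(0, -Inf), c(Inf, 0),
                                            c(0.2, -0.1), S2))
})

test_that("profiled Gaussian loglik agrees with dense evaluation to 1e-8", {
  set.seed(31)
  for (r in 1:6) {
    ped <- nuclear_family(paste0("d", r), n_kids = 3)
    phi <- kinship(ped)
    n <- nrow(phi)
    X <- cbind(1, rnorm(n))
    y <- rnorm(n)
    fit <- fit_polygenic(y, X, phi)
    ll <- dense_gaussian_loglik(y, X, phi, coef(fit), fit$sigma2_g,
                                fit$sigma2_e)
    expect_equal(fit$loglik, as.numeric(ll), tolerance = 1e-8)
  }
})

test_that("unrelated founders push the genetic variance to the boundary", {
  set.seed(8)
  n <- 120
  ped <- pedigree(fid = "u", id = paste0("u", 1:n), sex = "unknown",
                  proband = seq_len(n) == 1)
  y <- rnorm(n, sd = 1.5)
  fit <- fit_polygenic(y, matrix(1, n, 1), kinship(ped))
  expect_equal(fit$h2, 0)
  expect_equal(fit$sigma2_e, mean((y - mean(y))^2), tolerance = 1e-6)
})

test_that("redundant covariates leave the likelihood unchanged", {
  set.seed(9)
  ped <- nuclear_family("rc", n_kids = 4)
  phi <- kinship(ped)
  y <- rnorm(6)
  X <- matrix(1, 6, 1)
  f0 <- fit_polygenic(y, X, phi)
  f1 <- fit_polygenic(y, cbind(X, 0), phi)            # all-zero column
  f2 <- fit_polygenic(y, cbind(X, 2 * X[, 1]), phi)   # collinear column
  expect_equal(f1$loglik, f0$loglik, tolerance = 1e-9)
  expect_equal(f2$loglik, f0$loglik, tolerance = 1e-9)
})

test_that("polygenic fit recovers simulated heritability across sib-pairs", {
  set.seed(12)
  peds <- lapply(1:100, function(k) nuclear_family(paste0("s", k), 2))
  ped <- do.call(rbind, peds)
  phi <- kinship(ped)
  A <- 2 * phi
  h2 <- 0.6
  y <- drop(t(chol(h2 * A + diag(1 - h2, nrow(A)))) %*% rnorm(nrow(A)))
  fit <- fit_polygenic(y, matrix(1, nrow(A), 1), phi)
  expect_lt(abs(fit$h2 - h2), 0.2)
  expect_true(fit$converged)
})

test_that("nested Gaussian models never lose likelihood", {
  set.seed(13)
  ped <- do.call(rbind, lapply(1:20, function(k) nuclear_family(paste0("n", k), 2)))
  phi <- kinship(ped)
  n <- nrow(phi)
  y <- rnorm(n)
  dos <- rbinom(n, 2, 0.3)
  f0 <- fit_polygenic(y, matrix(1, n, 1), phi)
  f1 <- fit_polygenic(y, matrix(1, n, 1), phi, dosage = dos)
  expect_gte(f1$loglik, f0$loglik - 1e-9)
})

test_that("liability fit matches the probit closed form for unrelated singles", {
  set.seed(14)
  n <- 300
  status <- rbinom(n, 1, 0.25)
  phi <- diag(0.5, n)
  dimnames(phi) <- list(paste0("i", 1:n), paste0("i", 1:n))
  fit <- fit_liability(status, matrix(1, n, 1), phi, fam = paste0("i", 1:n))
  expect_equal(fit$h2, 0)  # unidentifiable -> fixed at 0
  expect_equal(unname(coef(fit)[1]), qnorm(mean(status)), tolerance = 1e-4)
})

test_that("zero heritability reduces the liability model to independent probits", {
  ped <- do.call(rbind, lapply(1:10, function(k) nuclear_family(paste0("p", k), 2)))
  phi <- kinship(ped)
  n <- nrow(phi)
  set.seed(15)
  status <- rbinom(n, 1, 0.4)
  X <- cbind(1, rnorm(n))
  fit <- fit_liability(status, X, phi, ped$fid, h2_fixed = 0)
  eta <- drop(X %*% coef(fit))
  direct <- sum(ifelse(status == 1, pnorm(eta, log.p = TRUE),
                       pnorm(-eta, log.p = TRUE)))
  expect_equal(fit$loglik, direct, tolerance = 1e-6)
})

test_that("non-variation and oversize pedigrees are handled as specified", {
  ped <- nuclear_family("q", 2)
  phi <- kinship(ped)
  fit <- fit_liability(rep(1, 4), matrix(1, 4, 1), phi, ped$fid)
  expect_false(fit$estimable)
  big <- pedigree(fid = "b", id = paste0("b", 1:30), sex = "unknown",
                  proband = seq_len(30) == 1)
  expect_error(
    fit_liability(rep(c(0, 1), 15), matrix(1, 30, 1), kinship(big),
                  fam = rep("b", 30)),
    "more than 25")
})

test_that("ascertainment weights rank affected and probands higher", {
  sim <- simulate_families(family_sim_config(template = "random",
                                             n_families = 15, n_members = 6,
                                             seed = 2))
  tr <- ascertainment_weights(sim$traits, sim$ped)
  byst <- tapply(tr$w, tr$any_cancer, mean)
  expect_gt(byst[["1"]], byst[["0"]])
  # degenerate branch: all unaffected
  ped <- nuclear_family("deg", 2)
  tr0 <- trait_table(ped)
  expect_warning(out <- ascertainment_weights(tr0, ped), "set to 0")
  expect_true(all(out$w == 0))
})

test_that("LRT is invariant under affine rescaling of covariates", {
  set.seed(16)
  ped <- do.call(rbind, lapply(1:15, function(k) nuclear_family(paste0("a", k), 2)))
  phi <- kinship(ped)
  n <- nrow(phi)
  y <- rnorm(n)
  dos <- rbinom(n, 2, 0.3)
  cov1 <- rnorm(n, 50, 10)
  lrt <- function(cv) {
    X <- cbind(1, cv)
    2 * (fit_polygenic(y, X, phi, dosage = dos)$loglik -
           fit_polygenic(y, X, phi)$loglik)
  }
  expect_equal(lrt(cov1), lrt(3 * cov1 - 100), tolerance = 1e-6)
})

test_that("association scan flags monomorphic variants and corrects within list", {
  ped <- fig1_pedigrees()
  cs <- table3_callset()
  geno <- cbind(cs$geno, `9:999:A:T` = 0)  # monomorphic column
  v <- rbind(cs$variants,
             data.frame(chrom = "9", pos = 999L, ref = "A", alt = "T",
                        rsid = NA, pop_maf = NA, gene = "MONO",
                        func_class = NA, exonic_class = NA, sift = NA,
                        polyphen = NA, gerp = NA, regulome = NA,
                        stringsAsFactors = FALSE))
  traits <- ascertainment_weights(trait_table(ped), ped)
  sc <- variant_association_scan(v, geno, traits, ped,
                                 outcomes = "age_onset_cancer")
  mono <- sc[sc$gene == "MONO", ]
  expect_false(mono$testable)
  expect_identical(mono$note, "monomorphic")
  m <- sum(sc$testable)
  expect_equal(m, 8)
  ok <- sc[sc$testable, ]
  expect_equal(ok$q_value, pmin(1, m * ok$p_value))
  expect_true(all(diff(ok$p_value) >= 0))  # sorted by p
})

test_that("a strong planted liability variant has the smallest scan p-value", {
  sim <- simulate_families(family_sim_config(
    template = "random", n_families = 15, n_members = 5, causal_maf = 0.15,
    causal_beta = 2, liability_h2 = 0.3, prevalence = 0.2, seed = 33))
  ped <- sim$ped
  geno <- sim$geno
  set.seed(34)
  for (k in 1:3)  # null decoys
    geno <- cbind(geno, rbinom(nrow(geno), 2, 0.2))
  keys <- c("S:1000000:A:G", paste0("N:", 1:3, ":A:G"))
  colnames(geno) <- keys
  v <- data.frame(chrom = sapply(strsplit(keys, ":"), `[`, 1),
                  pos = as.integer(sapply(strsplit(keys, ":"), `[`, 2)),
                  ref = "A", alt = "G",
                  gene = c("CAUSAL", paste0("DECOY", 1:3)),
                  stringsAsFactors = FALSE)
  traits <- ascertainment_weights(sim$traits, ped)
  sc <- variant_association_scan(v, geno, traits, ped,
                                 outcomes = "any_cancer", covariates = "w")
  best <- sc$gene[which.min(sc$p_value)]
  expect_identical(best, "CAUSAL")
})
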