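#' Configuration for family simulation
#'
#' Defaults describe the study conditions the family stage assumes: three
#' cancer-cluster pedigrees ascertained through an affected proband, a
#' lifetime any-cancer prevalence of 0.3, liability heritability 0.33
#' (twin-study scale for overall cancer liability), a rare causal allele
#' (founder frequency 1%) and, under the null, no genotype effect.
#'
#' @param n_families number of families (ignored for template `"fig1"`,
#'   which always yields the three study pedigrees).
#' @param template `"fig1"` (the three study families), `"fig1_ped1"`,
#'   `"fig1_ped2"`, `"fig1_ped3"` (replicates of one study family) or
#'   `"random"` (random three-generation families of about `n_members`).
#' @param n_members target size for random families.
#' @param causal_maf founder allele frequency of the simulated causal
#'   variant.
#' @param liability_h2 additive polygenic liability heritability in
#'   `[0, 1)`.
#' @param causal_beta liability-scale effect per copy of the causal
#'   allele.
#' @param prevalence population prevalence K of affection in `(0, 1)`.
#' @param ascertain redraw families until each has at least one affected
#'   member (proband-based sampling); the first affected member becomes
#'   the proband.
#' @param max_redraws bounded redraw attempts per family before erroring.
#' @param seed RNG seed; one stream drives the whole simulation.
#' @return config list of class `family_sim_config`.
#' @export
family_sim_config <- function(n_families = 3, template = "fig1",
                              n_members = 8, causal_maf = 0.01,
                              liability_h2 = 0.33, causal_beta = 0,
                              prevalence = 0.3, ascertain = TRUE,
                              max_redraws = 200, seed = 1) {
  stopifnot(causal_maf >= 0, causal_maf <= 1,
            liability_h2 >= 0, liability_h2 < 1,
            prevalence > 0, prevalence < 1, n_families >= 1)
  structure(list(n_families = n_families, template = template,
                 n_members = n_members, causal_maf = causal_maf,
                 liability_h2 = liability_h2, causal_beta = causal_beta,
                 prevalence = prevalence, ascertain = ascertain,
                 max_redraws = max_redraws, seed = seed),
            class = "family_sim_config")
}

# Random three-generation family structure of about n_members.
random_family_structure <- function(fid, n_members) {
  id <- character(0); father <- character(0); mother <- character(0)
  sex <- character(0)
  add <- function(s, fa = NA_character_, mo = NA_character_) {
    k <- length(id) + 1L
    id[k] <<- sprintf("%s-%d", fid, k)
    father[k] <<- fa; mother[k] <<- mo; sex[k] <<- s
    id[k]
  }
  f1 <- add("male"); m1 <- add("female")
  couples <- list(c(f1, m1))
  while (length(id) < n_members) {
    cp <- couples[[sample.int(length(couples), 1)]]
    s <- sample(c("male", "female"), 1)
    ch <- add(s, fa = cp[1], mo = cp[2])
    if (length(id) + 1 <= n_members && stats::runif(1) < 0.5) {
      sp <- add(if (s == "male") "female" else "male")
      couples <- c(couples, list(if (s == "male") c(ch, sp) else c(sp, ch)))
    }
  }
  gen <- integer(length(id))
  fa_i <- match(father, id)
  for (k in seq_along(id))
    gen[k] <- if (is.na(fa_i[k])) 1L else gen[fa_i[k]] + 1L
  # married-in founders sit in their spouse's generation
  for (cp in couples) {
    g <- max(gen[match(cp, id)])
    gen[match(cp, id)] <- g
  }
  age <- c(75, 48, 21, 21)[pmin(gen, 4)] + round(stats::runif(length(id), -4, 4))
  pedigree(fid = fid, id = id, father = father, mother = mother, sex = sex,
           affected_cancer = "no", affected_sarcoma = "no", age = age,
           onset_age = NA, proband = FALSE, genotyped = TRUE)
}

# Drop one biallelic variant through a family: founders draw alleles at
# frequency maf, children inherit one allele from each parent.
drop_variant <- function(ped, maf) {
  ord <- topo_order(ped)
  fa <- match(ped$father, ped$id)
  mo <- match(ped$mother, ped$id)
  a1 <- a2 <- integer(nrow(ped))
  for (i in ord) {
    if (is.na(fa[i])) {
      a1[i] <- stats::rbinom(1, 1, maf)
      a2[i] <- stats::rbinom(1, 1, maf)
    } else {
      a1[i] <- if (stats::runif(1) < 0.5) a1[fa[i]] else a2[fa[i]]
      a2[i] <- if (stats::runif(1) < 0.5) a1[mo[i]] else a2[mo[i]]
    }
  }
  a1 + a2
}

#' Simulate ascertained families under the liability model
#'
#' Generates pedigrees, a causal-variant genotype, and affection status
#' from the same generative model the liability fit assumes: founder
#' alleles at `causal_maf`, Mendelian gene dropping, liability
#' `L = beta g + a + e` with `a ~ MVN(0, 2 Phi h2)` and
#' `e ~ N(0, 1 - h2)`, affected iff `L > qnorm(1 - K)`. Under
#' ascertainment each family is redrawn until it contains an affected
#' member; the first affected member (in member order) becomes the
#' proband and is labelled sarcoma-affected (the study ascertains sarcoma
#' probands); other affected members are sarcoma-affected with
#' probability 1/2. Onset ages for affected members are drawn uniformly
#' between 15 and current age.
#'
#' @param cfg a [family_sim_config()].
#' @return list with `ped` (famped), `geno` (dosage matrix over genotyped
#'   members, one column, key `"S:1000000:A:G"`), `traits` (trait table),
#'   and `truth` (config plus per-individual liabilities, genetic values
#'   and dosages).
#' @export
simulate_families <- function(cfg) {
  set.seed(cfg$seed)
  thr <- stats::qnorm(1 - cfg$prevalence)
  fig1 <- fig1_pedigrees()
  structures <- switch(
    cfg$template,
    fig1 = split_families(fig1),
    fig1_ped1 = replicate_template(fig1, "1", cfg$n_families),
    fig1_ped2 = replicate_template(fig1, "2", cfg$n_families),
    fig1_ped3 = replicate_template(fig1, "3", cfg$n_families),
    random = lapply(seq_len(cfg$n_families), function(k)
      random_family_structure(sprintf("f%d", k), cfg$n_members)),
    stop("unknown template: ", cfg$template)
  )
  peds <- list(); dosages <- list(); liab <- list(); gen_val <- list()
  for (fp in structures) {
    eg <- eigen(2 * kinship(fp), symmetric = TRUE)
    rot <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0) * cfg$liability_h2),
                               nrow(fp))
    ok <- FALSE
    for (att in seq_len(cfg$max_redraws)) {
      g <- drop_variant(fp, cfg$causal_maf)
      a <- drop(rot %*% stats::rnorm(nrow(fp)))
      e <- stats::rnorm(nrow(fp), sd = sqrt(1 - cfg$liability_h2))
      L <- cfg$causal_beta * g + a + e
      aff <- L > thr
      if (!cfg$ascertain || any(aff)) { ok <- TRUE; break }
    }
    if (!ok)
      stop("ascertainment impossible: no affected member after ",
           cfg$max_redraws, " redraws (prevalence/effect too extreme)")
    fp$affected_cancer <- ifelse(aff, "yes", "no")
    fp$proband <- FALSE
    if (any(aff)) fp$proband[which(aff)[1]] <- TRUE
    sarc <- aff & (fp$proband | stats::runif(nrow(fp)) < 0.5)
    fp$affected_sarcoma <- ifelse(sarc, "yes", "no")
    fp$onset_age <- ifelse(aff & !is.na(fp$age),
                           round(15 + stats::runif(nrow(fp)) *
                                   pmax(0, fp$age - 15)), NA)
    fp$onset_age[!aff] <- NA
    peds[[length(peds) + 1L]] <- fp
    dosages[[length(dosages) + 1L]] <- stats::setNames(g, fp$id)
    liab[[length(liab) + 1L]] <- stats::setNames(L, fp$id)
    gen_val[[length(gen_val) + 1L]] <- stats::setNames(a, fp$id)
  }
  ped <- do.call(rbind, peds)
  dos <- unlist(dosages)
  key <- "S:1000000:A:G"
  gids <- ped$id[ped$genotyped]
  geno <- matrix(dos[gids], ncol = 1, dimnames = list(gids, key))
  list(ped = ped, geno = geno, traits = trait_table(ped),
       truth = list(config = cfg, dosage = dos, liability = unlist(liab),
                    genetic = unlist(gen_val), threshold = thr))
}

split_families <- function(ped) {
  lapply(unique(ped$fid), function(f) {
    fp <- ped[ped$fid == f, ]
    class(fp) <- c("famped", "data.frame")
    fp
  })
}

replicate_template <- function(ped, fid, n) {
  tmpl <- ped[ped$fid == fid, ]
  lapply(seq_len(n), function(k) {
    fp <- tmpl
    fp$fid <- sprintf("%s_r%d", fid, k)
    ren <- function(x) ifelse(is.na(x), NA, sprintf("r%d_%s", k, x))
    fp$id <- ren(fp$id); fp$father <- ren(fp$father); fp$mother <- ren(fp$mother)
    class(fp) <- c("famped", "data.frame")
    fp
  })
}

#' Configuration for case/control cohort simulation
#'
#' Defaults emulate the validation design: 560 cases and 1144 controls,
#' with the per-gene variant counts and allele frequencies implied by the
#' control side of the published burden tables (see
#' [default_cohort_genes()]), and no enrichment.
#'
#' @param n_cases,n_controls cohort sizes.
#' @param genes named list: each element `list(maf = <numeric>, class =
#'   <character>)` gives the per-variant control-population minor allele
#'   frequencies and variant class labels (`"deleterious"` or
#'   `"regulatory"`) for one gene.
#' @param enrichment_rho odds multiplier applied to the case allele
#'   frequency, `q' = rho q / (1 + (rho - 1) q)`; a scalar for all genes
#'   or a named vector (genes absent from the names get 1).
#' @param counts_only skip per-sample genotypes and simulate aggregate
#'   allele counts directly (same distribution, much faster).
#' @param seed RNG seed.
#' @return config list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_cases = 560, n_controls = 1144,
                              genes = default_cohort_genes(),
                              enrichment_rho = 1, counts_only = FALSE,
                              seed = 1) {
  stopifnot(n_cases > 0, n_controls > 0, all(unlist(enrichment_rho) > 0))
  structure(list(n_cases = n_cases, n_controls = n_controls, genes = genes,
                 enrichment_rho = enrichment_rho, counts_only = counts_only,
                 seed = seed),
            class = "cohort_sim_config")
}

#' Default cohort gene panel
#'
#' One entry per prioritized gene and variant class with a qualifying
#' variant in the published control cohort: the number of variants equals
#' the control qualifying-variant count and each variant's frequency is
#' the control minor count split evenly across them.
#'
#' @return named list suitable for [cohort_sim_config()].
#' @export
default_cohort_genes <- function() {
  tabs <- table45_counts()
  genes <- list()
  for (tb in tabs) {
    if (tb$control_variants == 0) next
    q <- tb$control_minor / (2 * tb$control_n * tb$control_variants)
    g <- genes[[tb$gene]]
    if (is.null(g)) g <- list(maf = numeric(0), class = character(0))
    g$maf <- c(g$maf, rep(q, tb$control_variants))
    g$class <- c(g$class, rep(tb$variant_class, tb$control_variants))
    genes[[tb$gene]] <- g
  }
  genes
}

#' Simulate case/control cohorts with optional gene enrichment
#'
#' Control minor-allele counts per variant are Binomial(2 n_controls, q);
#' case counts are Binomial(2 n_cases, q') with the case frequency scaled
#' on the odds scale, `q' = rho q / (1 + (rho - 1) q)`. With
#' `counts_only = FALSE`, per-sample dosages are drawn as Binomial(2, q)
#' (equivalent in aggregate).
#'
#' @param cfg a [cohort_sim_config()].
#' @return list with `annotation` (variant data frame), and either `case`
#'   / `control` callsets, or (counts mode) `case_counts` /
#'   `control_counts` named vectors keyed by variant.
#' @export
simulate_cohorts <- function(cfg) {
  set.seed(cfg$seed)
  ann <- list(); pos0 <- 0L
  for (gi in seq_along(cfg$genes)) {
    gene <- names(cfg$genes)[gi]
    spec <- cfg$genes[[gi]]
    nv <- length(spec$maf)
    if (nv == 0) next
    deleterious <- spec$class == "deleterious"
    ann[[gi]] <- data.frame(
      chrom = as.character(gi), pos = pos0 + seq_len(nv) * 1000L,
      ref = "A", alt = "G", rsid = NA_character_, pop_maf = spec$maf,
      gene = gene,
      func_class = ifelse(deleterious, "exonic", "intronic"),
      exonic_class = ifelse(deleterious, "nonsynonymous", NA_character_),
      sift = ifelse(deleterious, "deleterious", NA_character_),
      polyphen = ifelse(deleterious, "damaging", NA_character_),
      gerp = ifelse(deleterious, 2.0, NA_real_),
      regulome = ifelse(deleterious, NA_character_, "2"),
      stringsAsFactors = FALSE
    )
  }
  ann <- do.call(rbind, ann)
  rho <- vapply(ann$gene, function(g) {
    r <- cfg$enrichment_rho
    if (!is.null(names(r))) {
      if (g %in% names(r)) unname(r[[g]]) else 1
    } else as.numeric(r)
  }, numeric(1))
  q <- ann$pop_maf
  q_case <- rho * q / (1 + (rho - 1) * q)
  keys <- variant_key(ann)
  if (cfg$counts_only) {
    case_counts <- stats::rbinom(length(q), 2 * cfg$n_cases, q_case)
    control_counts <- stats::rbinom(length(q), 2 * cfg$n_controls, q)
    names(case_counts) <- names(control_counts) <- keys
    return(list(annotation = ann, case_counts = case_counts,
                control_counts = control_counts))
  }
  draw <- function(n, freqs) {
    g <- vapply(freqs, function(f) stats::rbinom(n, 2, f),
                numeric(n))
    if (is.null(dim(g))) g <- matrix(g, nrow = n)
    dimnames(g) <- list(sprintf("s%d", seq_len(n)), keys)
    g
  }
  case_g <- draw(cfg$n_cases, q_case)
  control_g <- draw(cfg$n_controls, q)
  rownames(case_g) <- sprintf("case%d", seq_len(cfg$n_cases))
  rownames(control_g) <- sprintf("ctrl%d", seq_len(cfg$n_controls))
  list(annotation = ann,
       case = list(variants = ann, geno = case_g),
       control = list(variants = ann, geno = control_g))
}

#' Burden tables from a simulated cohort pair
#'
#' Aggregates a [simulate_cohorts()] result into per-gene, per-class
#' burden tables using the stage-two qualifying rules (observed in the
#' cohort, combined MAF below `maf_max`).
#'
#' @param sim result of [simulate_cohorts()].
#' @param cfg the config used (for cohort sizes).
#' @param maf_max rarity ceiling.
#' @return list of `burden_table` objects.
#' @export
sim_burden_tables <- function(sim, cfg, maf_max = 0.05) {
  ann <- sim$annotation
  keys <- variant_key(ann)
  if (!is.null(sim$case_counts)) {
    ca <- sim$case_counts[keys]
    cb <- sim$control_counts[keys]
  } else {
    ca <- colSums(sim$case$geno)[keys]
    cb <- colSums(sim$control$geno)[keys]
  }
  cls <- ifelse(!is.na(ann$exonic_class) & ann$exonic_class == "nonsynonymous",
                "deleterious", "regulatory")
  combined <- (ca + cb) / (2 * (cfg$n_cases + cfg$n_controls))
  rare <- combined < maf_max
  tabs <- list()
  for (gene in unique(ann$gene)) for (vc in unique(cls[ann$gene == gene])) {
    sel <- ann$gene == gene & cls == vc & rare
    tabs[[paste(gene, vc, sep = ":")]] <- burden_table_from_counts(
      gene, vc,
      case_minor = sum(ca[sel & ca >= 1]),
      case_variants = sum(ca[sel] >= 1),
      case_n = cfg$n_cases,
      control_minor = sum(cb[sel & cb >= 1]),
      control_variants = sum(cb[sel] >= 1),
      control_n = cfg$n_controls)
  }
  tabs
}
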