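---
title: "Two-stage familial cancer risk-gene discovery: models, parameters, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage familial cancer risk-gene discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(famrisk)
```

## The procedure and its assumptions

famrisk implements a two-stage design for finding rare germline cancer
risk variants. Stage one works inside a handful of multigenerational
pedigrees ascertained through an affected proband: variants called in the
sequenced members are categorized, tested for association with four
cancer outcomes under polygenic models, and filtered by strict familial
segregation. Stage two validates the implicated genes in an independent
case/control cohort by rare-variant burden testing.

The design embodies strong assumptions worth stating plainly:

* **A shared familial variant.** Affected members of one family are
  assumed to carry the *same* risk variant. The segregation filter makes
  this literal: complete penetrance (every carrier affected) and full
  detectance (every genotyped affected member a carrier) within a single
  family. Variants with incomplete penetrance, later onset than the
  observation time, or recurrence across families are deliberately
  discarded; sensitivity is traded for specificity.
* **Additive polygenic background.** Residual familial correlation is
  modelled through 2Φσ²g with Φ the kinship matrix — autosomal additive
  inheritance only (no dominance, household, X-linked or mitochondrial
  components).
* **Liability threshold for binary outcomes.** Affection is a
  deterministic threshold on a latent Gaussian liability. The threshold is
  absorbed into the probit intercept; total liability variance is fixed
  at 1 so the genetic component h² is directly the liability-scale
  heritability.
* **Ascertainment correction by covariate.** Proband-based sampling
  inflates familial risk. A bias-reduced (Jeffreys-penalized) probit
  regression of affection on the proband flag and relatedness to the
  proband supplies a per-individual score used as a fixed-effect
  covariate `w`. This is a pragmatic correction, not a full
  ascertainment-corrected likelihood; the exact construction is
  configurable (`ascertainment_weights(design=)`) because no canonical
  form exists for it.

## Stage-one components

**Categorization** assigns overlapping labels: `rare_private` (no rsID),
`known_rare` (rsID with reference-population MAF ≤ 0.01) and
`candidate_gene` (inside a gene span padded ±25 kb, the window in which
off-target reads can still capture regulatory variants). All labels are
retained; the primary label follows the precedence rare_private >
known_rare > candidate_gene. Bonferroni correction is applied *within*
each category list — the lists are analysed as separate hypotheses
families, so `m` is the number of testable variants in the list being
scanned.

**The Gaussian fit** (`fit_polygenic`) maximizes the exact likelihood of
y = Xβ + g + e with Var = 2Φσ²g + Iσ²e. Rather than a multi-start
quasi-Newton search over (β, log σ²), the implementation rotates into the
eigenbasis of 2Φ, profiles β and the total variance in closed form, and
optimizes the single heritability ratio on [0, 1) by golden-section with
an explicit boundary check at 0. This is deterministic, needs no
restarts, and is exact to optimizer tolerance (the profile is unimodal in
practice and cheap to evaluate); the dense-matrix likelihood oracle in
the test suite pins it to 1e-8.

**The liability fit** (`fit_liability`) evaluates each pedigree's
contribution as the MVN rectangle probability of its affection pattern.
Rectangles are computed by the Genz quasi-Monte-Carlo algorithm at
absolute tolerance 1e-4 with the RNG state pinned to a fixed internal
seed around each call, so the likelihood surface is deterministic and
smooth enough for bounded quasi-Newton (L-BFGS-B) over (β, h²) with three
deterministic starts. Fixed-effect bounds of ±20 on the probit scale
prevent divergence under separation. Inside the association scan, the
full (dosage) model warm-starts from the null solution with the dosage
effect at 0 — this both saves two restarts and guarantees the
likelihood-ratio statistic is nonnegative by construction. Pedigrees with
more than 25 phenotyped members are refused (integration dimension cap);
with no variation in affection the fit is flagged non-estimable rather
than raising an error, since small fixtures can make "any sarcoma"
degenerate.

**Numerical details.** Onset ages are set to 0 for unaffected individuals
*before* the Blom inverse-normal transform (c = 3/8); the resulting heavy
ties at 0 take averaged ranks. Covariates are standardized inside the
scan (the LRT is invariant under affine rescaling; raw ages of 15-90 on a
probit scale otherwise slow the optimizer badly). Λ = 2(ℓ₁ − ℓ₀) is
clipped at 0 and referred to χ²₁; monomorphic variants are flagged
non-testable and excluded from the Bonferroni multiplier.

## Stage-two components

A variant qualifies for a gene's burden table if annotated to the gene,
in class (`deleterious`: stop-gain/stop-loss or nonsynonymous with SIFT
*deleterious* and PolyPhen-2 *damaging*; `regulatory`: RegulomeDB rank
≤ 2), and rare — MAF < 0.05 on the combined cohorts by default (the
reference population for the rarity cut is not canonical; `maf_source =
"pop"` switches to the annotation MAF). A variant contributes to a
cohort's counts only if observed there, and the major-allele denominator
is 2 × cohort size × number of qualifying variants in that cohort minus
the minor count. This "slot" convention is the package default because it
exactly reproduces the odds ratios that can be checked from published
allele-count tables (e.g. 12/5588 vs 3/6861 → OR 4.91).

The one-sided Fisher exact test sums hypergeometric point probabilities
over the support via log-gamma factorials with log-sum-exp accumulation;
the default tail is the one toward the observed effect, since published
analyses report significant depletions as well as enrichments. A zero
margin yields p = 1. Odds ratios are sample cross-product ratios; a zero
control cell with case carriers is reported as infinite (printed zeros in
that situation are treated as table typos), a zero case cell as 0, and an
empty table as untestable. The Bonferroni multiplier is the number of
testable tables per class by default; a fixed multiplier is available
because published q-values are consistent with either convention in
different rows.

## The annotation-filter direction question

The stage-one deleteriousness filter follows its source protocol
literally: GERP score *below* 3. GERP conventionally flags evolutionary
constraint (hence putative deleteriousness) at *high* scores, so the
literal reading likely inverts the intended filter. Both directions are
implemented (`gerp_direction = "lt"` or `"ge"`); the default is the
literal rule, documented here rather than silently "corrected". The
burden-stage deleterious definition does not use GERP at all, so stage
two is unaffected.

## What the synthetic-data module emulates — and what it does not

`simulate_families()` draws founder alleles at a configurable frequency,
gene-drops them through the pedigree, adds an additive polygenic term
a ~ MVN(0, 2Φh²) and residual e ~ N(0, 1−h²), and thresholds the
liability at qnorm(1−K). Defaults encode the study conditions: the three
encoded study pedigrees as templates, lifetime any-cancer prevalence
K = 0.3, liability heritability 0.33 (the scale reported by twin studies
for overall cancer), causal MAF 0.01 and, under the null, β = 0.
Ascertainment redraws each family until it contains an affected member;
the first affected member becomes the (sarcoma-affected) proband.
`simulate_cohorts()` draws per-variant allele counts binomially, scaling
the case frequency on the odds scale, q′ = ρq/(1 + (ρ−1)q); the default
gene panel mirrors the control side of the published burden tables
(560/1144 cohort sizes).

The generator deliberately omits: linkage disequilibrium between
variants, population stratification, genotyping or sequencing error,
variant-calling artefacts, age-dependent penetrance, and non-additive
genetic architecture. Passing tests therefore demonstrate that the
*statistical machinery* is correct under its own assumptions — they do
not certify performance on real cohorts, where those omitted features
are the dominant practical difficulties. In particular, the liability
generator and the liability fit share the same model family, so
parameter-recovery tests validate the estimator, not the model.

## Problem sizes and frozen test bands

The test suite sizes were chosen to give informative checks at desktop
scale: exact-test agreement with brute-force enumeration is exhaustive
over every 2×2 table with total ≤ 44 and stratified over random margins
for totals up to 200 (1e-12 tolerance); kinship is checked against 20,000
gene drops within 3 Monte-Carlo standard errors; burden type-I error uses
2,000 null cohort replicates at the validation cohort sizes; liability
heritability recovery uses 200 five-member pedigrees at h² ∈ {0, 0.5}
with acceptance bands (≤ 0.2, and [0.3, 0.7]) frozen from the sampling
spread observed for this design; scan-null uniformity uses 500 variants
on ~250 individuals with a Kolmogorov-Smirnov test at α = 0.01; planted
gene recovery uses ρ = 5 at a fixed seed.

## Known limitations

* The probit-weight design matrix (proband flag + relatedness) is a
  reconstruction; numerical equality with weights produced by other
  software is not claimed, and stage-one p-values on real data will
  differ in detail from any particular reference implementation.
* The liability fit's quasi-Monte-Carlo tolerance (1e-4 per pedigree)
  bounds the achievable precision of log-likelihood differences; LRT
  p-values far below ~1e-6 from small fixtures should not be
  over-interpreted.
* Burden testing has no covariate adjustment or relatedness handling;
  cohorts are assumed ancestry-matched upstream.
* Indel normalization (left-alignment) is off by default: callset
  intersection uses exact key equality, matching an exact-allele-match
  merge; discordant representations across callers must be normalized
  beforehand if present.
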