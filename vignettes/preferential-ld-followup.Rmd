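---
title: "Trans-ethnic GWAS follow-up with preferential LD tagging"
author: "prefld"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trans-ethnic GWAS follow-up with preferential LD tagging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

A GWAS-discovered variant is usually a proxy of the causal variant, not
the causal variant itself. When a hit discovered in one population (most
often of European ancestry) is followed up in a population with
shorter-range LD (such as African-ancestry populations), the causal
variant is often rarer than the hit and only weakly correlated with it —
r² well below the 0.6 that conventional LD-based fine-mapping uses as a
selection floor. Absolute LD then carries little information about which
catalog variant drives the signal.

`prefld` implements the *preferential LD* approach to this problem. The
premise is relative, not absolute: even when r²(hit, causal) is small,
the hit should still tag the causal variant **better than almost every
other variant the GWAS interrogated**. Tagging specificity, rather than
tagging strength, is the ranking signal.

## The procedure

For each GWAS hit that replicates in the follow-up study (nominal
p < 0.05 by allelic-dosage logistic regression, effect direction
consistent with the discovery report), four steps are applied to a phased
follow-up variant catalog:

1. **Candidate selection** (`select_candidates`). Catalog variants within
   `window_radius` (default 500,000 bp per side, i.e. a 1 Mb interval
   centered on the hit) that were *not* interrogated by the GWAS platform
   and are *rarer* than the hit (strict MAF inequality in the follow-up
   catalog). The rarity filter can be switched off (`freq_rule = "off"`):
   allele frequencies shift between populations, and a variant that is
   rarer than the hit in the discovery population need not be rarer in
   the follow-up catalog.
2. **Preferential LD statistic** (`preferential_ld_statistic`). For a
   candidate c, the share of platform variants v in the window with
   r²(v, c) ≥ r²(hit, c). The hit ties with itself, so the statistic
   lives in [1/P, 1], P being the platform count in the window (hit
   included). 1/P means *no* interrogated variant tags the candidate as
   well as the hit — maximal specificity.
3. **LD permutation test** (`permutation_test`). Candidates must be in
   non-random LD with the hit: the candidate's allele column is permuted
   across haplotypes (preserving its frequency, destroying LD) and
   p = (1 + #{r²_perm ≥ r²_obs}) / (1 + n_perm). Candidates with
   p ≥ 0.05 are dropped.
4. **Sorting score and ranking** (`sorting_score`, `rank_candidates`).
   Tagging specificity is combined with functional importance: the score
   is the equal-weight mean of two in-set percentile ranks — of the
   (small is good) preferential LD statistic and of the (large is good)
   conservation score. Score significance is assessed by permuting the
   conservation values across candidates. Ranking is by ascending score.

Downstream, every catalog variant in the window present in the
case-control panel is tested by dosage logistic regression, the
study-wide threshold is a Bonferroni correction at the *effective* number
of independent tests, and each locus is evaluated by comparing the hit,
the best tested marker overall, and the best preferential LD candidate
(`locus_rank`, `summarize_improvement`).

## Statistical components

**LD engine.** r² is computed from phased haplotype counts
(Haploview-style), not from genotype correlation: with n haplotypes and
counts s_x, s_y, s_xy, r² = (n·s_xy − s_x·s_y)² / (s_x(n−s_x)·s_y(n−s_y)).
The count form is exactly symmetric in its arguments and equals the
squared Pearson correlation of the allele indicators. Monomorphic columns
get r² := 0 with a flag rather than NaN, so preferential-LD denominators
stay defined.

**Permutation null.** Uniformly permuting a binary column against a fixed
binary column makes the (1,1)-haplotype overlap count hypergeometric, so
the null is sampled directly with one `rhyper` draw per permutation —
distributionally identical to an explicit shuffle (a test cross-checks
the two routes) and O(1) per permutation. Because the null statistic is
discrete, p-values are mildly conservative at small haplotype counts;
calibration is checked by simulation in the test suite.

**Association.** `dosage_logistic` fits
logit P(case) = β₀ + β·dosage + covariates (+ conditioning dosages) with
`stats::glm`, reporting exp(β) per alternate allele and the Wald p.
Covariates are screened by covariate-only models at p < 0.1
(likelihood-ratio test, so factor covariates are handled whole).
ER-subtype analyses contrast subtype cases against *all* controls; cases
of the other or unknown subtype are excluded from that contrast. This
contrast is a documented choice — published subtype analyses often do not
state whether other-subtype cases are dropped or kept as non-cases.
Conditional analysis adds the conditioning variants' dosages as
covariates; an exactly collinear conditioning set is reported as a
flagged degenerate result (p sentinel 1), not an error.

**Effective number of tests.** `effective_tests` uses the Li–Ji-style
eigenvalue estimator: M_eff = Σ_i [λ_i ≥ 1] + (λ_i − ⌊λ_i⌋) over the
eigenvalues of the dosage correlation matrix. The identity matrix gives
M, a perfectly correlated block gives 1. Eigenvalues within 1e-9 of an
integer are snapped before applying ⌊·⌋ (the estimator is discontinuous
at integers and exact-correlation blocks land on them up to rounding).
For large variant sets the matrix is blocked by chromosome and the block
estimates are summed (`effective_tests_blocked`); inter-chromosome dosage
correlation is ~0, and a single eigendecomposition of tens of thousands
of variants would be intractable. Which eigenvalue estimator the original
analysis used is not derivable from the published account; the estimator
here is a fixed, documented default.

## The synthetic world

`simulate_panels` draws a shared founder pool and builds each
population's haplotypes as founder mosaics; the per-bp switch rate
controls LD decay, and the follow-up population gets the higher rate
(shorter LD). This is deliberately a transparent mosaic model, not a
coalescent: it realizes "same variants, different LD" — the one property
the method depends on — at negligible cost, and it makes LD decay
monotone in a single parameter.

Defaults state the regime the method targets (an FGFR2-like locus):

| parameter | default | meaning |
|---|---|---|
| `n_variants` | 300 | catalog variants per 1 Mb region |
| `n_hap_followup` | 492 | follow-up catalog (246 diploids, a realistic reference-panel size) |
| `n_hap_discovery` | 500 | discovery-population panel |
| `switch_rate_discovery` | 2e-6/bp | long-range LD |
| `switch_rate_followup` | 8e-6/bp | short-range LD |
| `hit_maf` | 0.45 | common GWAS hit |
| `causal_maf` | 0.08 | rare causal variant in the follow-up catalog |
| `causal_maf_discovery` | 0.40 | the same variant is common at discovery |
| `target_r2_discovery` | 0.6 | strong discovery tagging |
| `target_r2_followup` | 0.10 | weak follow-up tagging (0.05–0.15 band) |
| `odds_ratio` | 1.5 | per-allele effect |
| `prevalence` | 0.10 | baseline risk for the logistic intercept |
| `n_cases`, `n_controls` | 4000, 4000 | follow-up study size |
| `platform_fraction` | 0.25 | share of catalog variants on the GWAS platform |
| `conservation_boost` | 0.6 | additive bump at the causal site over a Beta(1.5, 15) background |

Two defaults deserve comment. First, the causal variant must be *common*
in the discovery population: r² between loci with MAFs 0.08 and 0.45 is
bounded at ~0.11, so a discovery r² of 0.6 is arithmetically impossible
unless the frequencies are comparable there — exactly the trans-ethnic
frequency shift the method exploits. Second, the hit and causal columns
are planted by conditional Bernoulli draws against the per-population
targets with rejection sampling (MAF tolerance ±0.03, r² within ±50% of
target, retry cap 1000), so realized values are recorded in the
`TruthRecord` rather than assumed.

Phenotypes are sampled retrospectively: diploid individuals are formed by
pairing haplotypes with replacement, disease risk is logistic in the
causal dosage with the intercept solved numerically for the configured
prevalence, and sampling continues until the case and control quotas are
met — matching a case-control design. Null covariates (study site, age)
are attached so covariate screening is exercisable.

What the generator does *not* emulate: admixture LD, genotyping or
imputation error (dosages are exact), selection, realistic site frequency
spectra, multi-signal loci, and ER-subtype-specific effects (subtype
labels are random among cases). A green end-to-end test therefore
establishes that the pipeline recovers a planted single causal variant
under clean weak-tagging LD structure — not that it is robust to
imputation noise or allelic heterogeneity.

## Numerical and design choices

* "Tags better than or as well as" uses ≥ on r², so ties count against
  the candidate (conservative). The hit is included in the denominator's
  platform set, fixing the statistic's floor at 1/P; whether the original
  method counts the hit is not stated, and this choice makes the floor
  deterministic.
* Permutation p-values use the add-one form (1 + exceedances)/(1 + n),
  never exactly zero; r² comparisons in the permutation test use a 1e-12
  slack so exact ties are not lost to floating-point noise.
* Percentile ranks use mid-ranks for ties, (rank − 0.5)/n; a single
  candidate degenerates to 0.5. The combiner is pluggable
  (`rank_mean` default, `rank_product` alternative, arbitrary weights)
  because the original sorting-score formula is not published in the
  account this package works from.
* Candidate ranking breaks score ties by ascending preferential LD
  statistic, then ascending position — deterministic and order-invariant.
* Locus rank k uses strict-inequality counting (1 + #{p strictly
  smaller}), so a candidate tying the global minimum ranks 1.
* Variant positions are 1-based inclusive (VCF convention); a window of
  radius w around p is [p−w, p+w]. Multi-allelic records are skipped with
  a warning by default or split into biallelic records on request; in a
  split record the other alternate alleles count as reference.
* Replication classification falls back to the p-value alone, flagged,
  when the discovery direction is unavailable.
* The merge-stage QC applies its MAF rule (< 0.6%) in either input set,
  mirroring the stated "either set" scope of the INFO < 0.5 rule; the
  frequency-difference rule (> 0.15) is symmetric by construction.

## Scale of the bundled checks

The acceptance tests run the full-size stated regime (4000 + 4000, 50
replicates); module tests use scaled-down panels (200–300 haplotypes,
400–1600 individuals) where the property under test is mechanical rather
than statistical, and the LD permutation/sorting tests use 200–1000
permutations to stay inside the suite's time budget.

## Limitations

The approach follows up *one* signal per hit; loci with multiple
independent risk variants need conditional decomposition first. Its
success presumes the causal variant is present in the catalog and that
the hit is its best platform tag in the follow-up population — both
assumptions weaken when the catalog is small or the platform was designed
for another population. The bundled published locus table supports
summary-level reproduction only; individual-level consortium results are
not reproducible from public data, and no numeric acceptance target is
claimed for them.
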