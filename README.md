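# prefld — trans-ethnic GWAS follow-up with preferential LD tagging

GWAS hits are usually proxies of causal variants, and a proxy discovered
in one population often tags the causal variant poorly in another: in
African-ancestry populations, where LD is shorter-range, the causal
variant is frequently rarer than the hit and correlated with it at
r² « 0.6. Selecting fine-mapping candidates by *absolute* LD with the hit
then fails. `prefld` is for statistical geneticists running that
follow-up: it prioritizes catalog variants by how *specifically* the hit
tags them, tests them by allelic-dosage logistic regression with
study-wide correction, and evaluates whether the prioritized candidates
beat the hit at each locus.

## The core statistic

For a GWAS hit *h* and a candidate *c* drawn from a phased variant
catalog (within ±500 kb of *h*, not interrogated by the GWAS platform,
and rarer than *h*), the **preferential LD statistic** is

    PL(c) = #{ v ∈ platform in window : r²(v, c) ≥ r²(h, c) } / P ,

the share of the P GWAS-interrogated variants in the window that tag *c*
at least as well as the hit does (the hit ties with itself, so
PL ∈ [1/P, 1]). PL = 1/P says the hit tags *c* better than every other
interrogated variant — strong evidence that *c* drives the hit's signal
even when r²(h, c) itself is small. Candidates must also show non-random
LD with the hit (permutation test on the haplotype r²) and are ranked by
a sorting score: the mean of the in-set percentile ranks of PL (small is
good) and of evolutionary conservation (large is good). Downstream,
association uses logit P(case) = β₀ + β·dosage + covariates (Wald test,
OR = exp β), with the study-wide threshold α / M_eff where M_eff is the
Li–Ji eigenvalue-based effective number of independent tests
(e.g. 0.05 / 19,617 ≈ 2.55×10⁻⁶).

All of this runs identically on real inputs (phased VCF catalog, platform
id list, conservation TSV, dosage/phenotype/covariate tables) and on the
bundled founder-mosaic simulator, which plants a causal variant that is
common and well tagged in the discovery population but rare (MAF ~0.08)
and weakly tagged (r² ~0.1) in the follow-up population.

## Worked example

```r
library(prefld)

cfg <- sim_config(seed = 7)                      # the stated weak-tagging regime
sim <- simulate_panels(cfg)                      # two populations + planted truth
conservation <- simulate_conservation(sim$followup, sim$truth, cfg)
cc <- simulate_phenotypes(sim$followup, sim$truth, cfg)  # 4000 cases / 4000 controls

hits <- data.frame(id = sim$truth$hit_id, phenotype = "overall",
                   discovery_population = "European ancestry",
                   risk_allele = "alt", reported_direction = 1)
report <- run_followup(sim$followup, sim$platform, conservation, cc, hits,
                       config = followup_config(n_perm = 1000, seed = 7))
print(report)
```

```
Follow-up run: 1/1 hit(s) replicated
  276 variant(s) tested, M_eff = 184.0, study-wide cutoff = 0.000272
  improved loci: 1/1 (100.0%); top-10 among improved: 1 (100%)
```

The hit replicated (p < 0.05, consistent direction), 276 window variants
were tested, and the correlation-adjusted Bonferroni cutoff is
0.05 / 184 ≈ 2.7×10⁻⁴. The top-ranked candidates:

```r
cand <- report$loci[[1]]$candidate_set$candidates
head(cand[order(cand$rank), c("id", "maf", "r2_to_hit", "pl_stat",
                              "perm_p", "sort_score", "rank")], 3)
```

```
          id        maf  r2_to_hit    pl_stat      perm_p sort_score rank
 snp_0615983 0.09146341 0.10619570 0.01388889 0.000999001 0.01162791    1
 snp_0615891 0.03048780 0.01823583 0.02777778 0.003996004 0.08720930    2
 snp_0570696 0.21341463 0.04708196 0.02777778 0.000999001 0.11046512    3
```

The rank-1 candidate is the planted causal variant (`sim$truth$causal_id`
is `snp_0615983`): MAF 0.09 versus the hit's 0.45, r² to the hit only
0.106 — far below any absolute-LD selection floor — yet its PL statistic
is 1/72 ≈ 0.0139, the floor: *no* platform variant tags it as well as the
hit. Its LD permutation p is 1/1001 (the add-one minimum at 1000
permutations) and it also carries the locus's smallest association
p-value.

## The analysis workflow

`analysis/` holds the numbered workflow the package was built around;
each script is a thin driver over package functions, reads its
predecessors' files, and writes tables under `results/analysis/`
(bulky intermediates go to `scratch/`):

1. `01_simulate.R` — five independent synthetic loci in the weak-tagging
   regime, written as VCF/TSV in the same formats real data would use.
2. `02_replicate.R` — covariate screening and hit replication; only
   replicating loci continue.
3. `03_candidates.R` — candidate selection, PL statistics, LD permutation
   filter, conservation-aware sorting and ranking.
4. `04_association.R` — window-wide dosage regression, M_eff and the
   study-wide cutoff, conditional analysis on each locus's top marker.
5. `05_evaluate.R` — per-locus best-marker comparison, QQ points, and the
   headline summaries recomputed from the bundled published locus table.

Run them in order from the repository root:
`for s in analysis/0*.R; do Rscript "$s"; done`

## Acceptance script

`scripts/acceptance.R` re-runs the package's end-to-end computation from
scratch: it simulates several independent follow-up loci at the stated
regime under the given seed, runs replication gating, preferential LD
scoring, association and evaluation for each, prints the per-locus
outcome (planted-causal rank, PL floor, effective-test cutoff), and
writes the target report as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
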