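#!/usr/bin/env Rscript
# Step 3: preferential LD candidate selection and prioritization.
#
# For each replicated hit: catalog variants within 500 kb that were not
# interrogated by the GWAS platform and are rarer than the hit are
# candidates; each gets the preferential LD statistic (share of platform
# variants tagging it at least as well as the hit; floor 1/P), an LD
# permutation test (non-random LD with the hit), and a sorting score
# combining tagging specificity with conservation. Candidates are ranked
# by the score.

source("analysis/00_common.R")

hits <- read_tsv_input(file.path(DATA_DIR, "hits_manifest.tsv"))
repl <- read_tsv_input(result_path("replication.tsv"))

for (i in seq_len(nrow(hits))) {
  h <- hits[i, ]
  if (!repl$replicated[repl$locus == h$locus]) {
    cat(sprintf("locus %d (%s) did not replicate; skipped\n",
                h$locus, h$id))
    next
  }
  catalog <- read_haplotypes(locus_path(h$locus, "followup_catalog.vcf"),
                             population = "followup")
  platform <- read_platform(locus_path(h$locus, "platform.txt"))
  conservation <- read_conservation(locus_path(h$locus, "conservation.tsv"))
  truth <- read_tsv_input(locus_path(h$locus, "truth.tsv"))

  hit <- gwas_hit(h$id, phenotype = h$phenotype,
                  discovery_population = h$discovery_population,
                  reported_direction = h$reported_direction)
  cset <- select_candidates(catalog, hit, platform,
                            window_radius = 500000L)
  cat(sprintf("locus %d (%s): %d candidates from %d catalog variants in the window (%d platform variants)\n",
              h$locus, h$id, nrow(cset$candidates),
              cset$n_catalog_in_window, cset$n_platform_in_window))
  cset <- score_candidates(cset, catalog, conservation, n_perm = 1000L,
                           seed = locus_seed(h$locus) + 1L)
  cat(sprintf("  %d candidate(s) dropped by the LD permutation filter\n",
              cset$n_filtered_perm))
  cand <- cset$candidates[order(cset$candidates$rank), ]
  write_tsv_output(cand, result_path(paste0("candidates_", h$id, ".tsv")),
                   comments = sprintf("ranked candidates around %s", h$id))
  k <- match(truth$causal_id, cand$id)
  if (!is.na(k))
    cat(sprintf("  planted causal %s: rank %d, PL statistic %.4f (floor %.4f), permutation p %.3g\n",
                truth$causal_id, cand$rank[k], cand$pl_stat[k],
                1 / length(cset$platform_in_window), cand$perm_p[k]))
}
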