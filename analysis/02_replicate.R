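#!/usr/bin/env Rscript
# Step 2: replication of the GWAS hits in the follow-up study.
#
# Covariates are screened with covariate-only logistic models (kept at
# p < 0.1), then each hit is tested by allelic-dosage logistic regression.
# A hit replicates when p < 0.05 with direction consistent with the
# discovery report; only replicated hits proceed to candidate selection.

source("analysis/00_common.R")

hits <- read_tsv_input(file.path(DATA_DIR, "hits_manifest.tsv"))

rows <- lapply(seq_len(nrow(hits)), function(i) {
  h <- hits[i, ]
  cc <- read_locus_cc(h$locus)
  covs <- screen_covariates(cc, h$phenotype, alpha = 0.1)
  hit <- gwas_hit(h$id, risk_allele = h$risk_allele,
                  phenotype = h$phenotype,
                  discovery_population = h$discovery_population,
                  reported_direction = h$reported_direction)
  res <- dosage_logistic(cc, hit$id, hit$phenotype, covariates = covs)
  replicated <- classify_replication(res, hit, alpha = 0.05)
  cat(sprintf("locus %d, %s: OR %.4f, p %.3g -> %s\n", h$locus, hit$id,
              res$or_estimate, res$p,
              if (replicated) "replicated" else "not replicated"))
  cbind(data.frame(locus = h$locus), as.data.frame(res),
        replicated = as.logical(replicated))
})
tab <- do.call(rbind, rows)
write_tsv_output(tab, result_path("replication.tsv"),
                 comments = "hit replication in the follow-up panel")
cat(sprintf("%d/%d hit(s) replicated; table at %s\n",
            sum(tab$replicated), nrow(tab),
            result_path("replication.tsv")))
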