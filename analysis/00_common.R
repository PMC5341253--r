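# Shared conventions for the numbered analysis scripts.
#
# The scripts form one workflow over a synthetic multi-locus follow-up
# study; each reads its predecessors' files, so any step can be rerun in
# isolation. Bulky intermediates (VCFs, dosage matrices) live under
# scratch/, small result tables under results/analysis/.
#
# As in a real follow-up, each simulated GWAS hit is tested first and only
# the replicating loci proceed; with the weakly tagged planted regime the
# per-locus replication power is moderate, so several loci are simulated.

suppressMessages(library(prefld))

DATA_DIR <- "scratch/analysis_data"
RESULT_DIR <- "results/analysis"
MASTER_SEED <- 20160913L
N_LOCI <- 5L

dir.create(DATA_DIR, recursive = TRUE, showWarnings = FALSE)
dir.create(RESULT_DIR, recursive = TRUE, showWarnings = FALSE)

locus_dir <- function(i) {
  d <- file.path(DATA_DIR, sprintf("locus_%02d", i))
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}
locus_path <- function(i, ...) file.path(locus_dir(i), ...)
result_path <- function(...) file.path(RESULT_DIR, ...)

locus_seed <- function(i) MASTER_SEED + 7919L * i

read_locus_cc <- function(i) {
  read_case_control(locus_path(i, "dosages.tsv"),
                    locus_path(i, "phenotype.tsv"),
                    locus_path(i, "covariates.tsv"))
}
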