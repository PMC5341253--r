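# Build a HaplotypePanel from a haplotype matrix with default metadata.
make_panel <- function(mat, pos = NULL, chrom = "1", ids = NULL,
                       population = "test") {
  m <- ncol(mat)
  if (is.null(pos)) pos <- seq_len(m) * 100L
  if (is.null(ids)) ids <- sprintf("v%03d", seq_len(m))
  haplotype_panel(
    data.frame(id = ids, chrom = chrom, pos = pos, ref = "A", alt = "C",
               stringsAsFactors = FALSE),
    mat, population = population)
}

# A column of n haplotypes with k alternate alleles at given indices.
col_with_ones <- function(n, idx) {
  x <- integer(n)
  x[idx] <- 1L
  x
}

# Write a small phased VCF from a list of record strings.
write_test_vcf <- function(records, samples = c("S1", "S2", "S3"),
                           path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records), path)
  path
}

vcf_record <- function(chrom, pos, id, ref, alt, gts) {
  paste(c(chrom, pos, id, ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}

# A small case-control panel with dosages planted by hand.
make_cc_panel <- function(dosages, case, er_status = NULL,
                          covariates = NULL) {
  n <- nrow(dosages)
  ids <- sprintf("ind%04d", seq_len(n))
  rownames(dosages) <- ids
  ph <- data.frame(sample_id = ids, case = case,
                   er_status = if (is.null(er_status)) "unknown"
                               else er_status,
                   stringsAsFactors = FALSE)
  cov <- if (is.null(covariates)) data.frame(row.names = ids) else {
    rownames(covariates) <- ids
    covariates
  }
  case_control_panel(dosages, ph, cov)
}
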