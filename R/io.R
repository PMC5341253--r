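#' Read phased haplotypes from a VCF region
#'
#' Loads biallelic records with phased GT in a 1-based inclusive region
#' into a [haplotype_panel()]. Coordinates follow the VCF convention; a
#' window of radius w around position p is `[p - w, p + w]` inclusive.
#'
#' @param vcf_path path to a VCF 4.x file with phased GT for all samples.
#' @param chrom chromosome to extract; `NULL` keeps all chromosomes.
#' @param start,end inclusive 1-based bounds of the region; `NULL` keeps
#'   everything on `chrom`.
#' @param population label stored on the returned panel.
#' @param multiallelic `"skip"` (default) drops multi-allelic records with
#'   a warning; `"split"` expands them into one biallelic record per
#'   alternate allele.
#' @param missing_gt `"drop"` (default) removes variants with any missing
#'   genotype and counts them; the catalog is assumed complete-phased.
#' @return A `HaplotypePanel`. A region beyond the last record gives an
#'   empty panel (0 variants), not an error. The number of variants
#'   dropped for missing genotypes is in `attr(panel, "n_dropped_missing")`.
#' @export
read_haplotypes <- function(vcf_path, chrom = NULL, start = NULL, end = NULL,
                            population = "unknown",
                            multiallelic = c("skip", "split"),
                            missing_gt = c("drop")) {
  multiallelic <- match.arg(multiallelic)
  missing_gt <- match.arg(missing_gt)
  vcf <- VariantAnnotation::readVcf(vcf_path, genome = "unknown")
  n_multi <- sum(lengths(VariantAnnotation::alt(vcf)) > 1L)
  if (n_multi > 0L && multiallelic == "skip") {
    warning(n_multi, " multi-allelic record(s) skipped")
    vcf <- vcf[lengths(VariantAnnotation::alt(vcf)) == 1L]
  }
  # index of the alternate allele each expanded record represents; other
  # alternate alleles count as reference in that record's biallelic view
  alt_index <- unlist(lapply(lengths(VariantAnnotation::alt(vcf)), seq_len))
  vcf <- VariantAnnotation::expand(vcf)  # flattens ALT to one per record
  rr <- SummarizedExperiment::rowRanges(vcf)
  df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(rr)),
                   pos = BiocGenerics::start(rr),
                   ref = as.character(VariantAnnotation::ref(vcf)),
                   alt = as.character(VariantAnnotation::alt(vcf)),
                   stringsAsFactors = FALSE)
  ids <- names(rr)
  if (is.null(ids)) ids <- rep("", nrow(df))
  fallback <- !nzchar(ids) | ids == "."
  ids[fallback] <- paste(df$chrom, df$pos, df$ref, df$alt,
                         sep = ":")[fallback]
  # expanded multi-allelic records share the original id: disambiguate
  dup <- duplicated(ids) | duplicated(ids, fromLast = TRUE)
  ids[dup] <- paste0(ids[dup], ":", df$alt[dup])
  df$id <- ids
  df <- df[, c("id", "chrom", "pos", "ref", "alt")]
  keep <- rep(TRUE, nrow(df))
  if (!is.null(chrom)) keep <- keep & df$chrom == chrom
  if (!is.null(start)) keep <- keep & df$pos >= start
  if (!is.null(end))   keep <- keep & df$pos <= end
  vcf <- vcf[keep]
  df <- df[keep, , drop = FALSE]
  alt_index <- alt_index[keep]

  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field: ", vcf_path)
  n_samp <- ncol(gt)
  if (nrow(df) == 0L) {
    return(haplotype_panel(
      data.frame(id = character(), chrom = character(), pos = integer(),
                 ref = character(), alt = character()),
      matrix(integer(), nrow = 2L * n_samp, ncol = 0L),
      population = population))
  }

  miss <- matrix(grepl(".", gt, fixed = TRUE), nrow = nrow(gt))
  unphased <- !miss & !matrix(grepl("|", gt, fixed = TRUE), nrow = nrow(gt))
  if (any(unphased)) {
    bad <- which(rowSums(unphased) > 0L)[1L]
    stop("unphased genotype at record '", df$id[bad],
         "' but phased haplotypes are required")
  }
  n_dropped <- 0L
  if (any(miss)) {
    drop_var <- rowSums(miss) > 0L
    n_dropped <- sum(drop_var)
    warning(n_dropped, " variant(s) dropped for missing genotypes")
    vcf <- vcf[!drop_var]
    gt <- gt[!drop_var, , drop = FALSE]
    df <- df[!drop_var, , drop = FALSE]
    alt_index <- alt_index[!drop_var]
  }

  # gt rows are variants; build a 2N x M haplotype matrix
  m <- nrow(df)
  hap <- matrix(0L, nrow = 2L * n_samp, ncol = m)
  if (m > 0L) {
    # gt is in column-major (variant, sample) order, so the per-variant alt
    # index recycles correctly across sample columns
    want <- rep(as.character(alt_index), times = n_samp)
    a1 <- substr(gt, 1L, 1L)
    a2 <- substr(gt, 3L, 3L)
    hap[seq(1L, 2L * n_samp, by = 2L), ] <- t(matrix(as.integer(a1 == want),
                                                     nrow = m))
    hap[seq(2L, 2L * n_samp, by = 2L), ] <- t(matrix(as.integer(a2 == want),
                                                     nrow = m))
  }
  ord <- order(df$chrom, df$pos)
  df <- df[ord, , drop = FALSE]
  hap <- hap[, ord, drop = FALSE]
  rownames(df) <- NULL
  out <- haplotype_panel(df, hap, population = population)
  attr(out, "n_dropped_missing") <- n_dropped
  out
}

#' Write a haplotype panel to a plain-text VCF
#'
#' Emits a minimal VCF 4.2 with phased GT so that a panel written and
#' re-read round-trips exactly (matrix and variant metadata).
#'
#' @param panel a `HaplotypePanel` with an even number of haplotype rows;
#'   consecutive row pairs become one diploid sample.
#' @param path output path (uncompressed `.vcf`).
#' @return `path`, invisibly.
#' @export
write_haplotypes <- function(panel, path) {
  stopifnot(inherits(panel, "HaplotypePanel"))
  n_hap <- nrow(panel$matrix)
  if (n_hap %% 2L != 0L) stop("panel must have an even number of haplotypes")
  n <- n_hap %/% 2L
  samples <- sprintf("S%04d", seq_len(n))
  v <- panel$variants
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=prefld",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  if (nrow(v)) {
    h1 <- panel$matrix[seq(1L, n_hap, by = 2L), , drop = FALSE]
    h2 <- panel$matrix[seq(2L, n_hap, by = 2L), , drop = FALSE]
    for (j in seq_len(nrow(v))) {
      gts <- paste0(h1[, j], "|", h2[, j])
      writeLines(paste(c(v$chrom[j], v$pos[j], v$id[j], v$ref[j], v$alt[j],
                         ".", "PASS", ".", "GT", gts), collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Read a GWAS platform variant list
#'
#' One variant identifier per line; `#` starts a comment. The returned
#' set is de-duplicated; order is irrelevant.
#'
#' @param path text file of ids.
#' @return character vector of unique ids (a warning if empty).
#' @export
read_platform <- function(path) {
  x <- readLines(path)
  x <- sub("#.*$", "", x)
  x <- trimws(x)
  x <- unique(x[nzchar(x)])
  if (!length(x)) warning("platform file '", path, "' contains no variant ids")
  x
}

#' Read per-position conservation scores
#'
#' @param path 3-column TSV: chrom, pos, score (header optional; '#'
#'   comments allowed).
#' @return data.frame with columns `chrom`, `pos`, `score`.
#' @export
read_conservation <- function(path) {
  x <- utils::read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE)
  if (is.character(x[[2]][1]) && is.na(suppressWarnings(as.numeric(x[[2]][1]))))
    x <- x[-1, , drop = FALSE]  # header row
  data.frame(chrom = as.character(x[[1]]), pos = as.integer(x[[2]]),
             score = as.numeric(x[[3]]), stringsAsFactors = FALSE)
}

#' Assemble a case-control panel from dosage, phenotype and covariate tables
#'
#' Inner-joins the three sources on sample id. Samples missing from any
#' source or with missing phenotype are dropped and counted; zero
#' overlapping samples or duplicated ids are errors.
#'
#' @param dosage_path TSV matrix: first column sample id, remaining columns
#'   per-variant allelic dosages in \[0, 2\].
#' @param pheno_path TSV with header: sample id first, a `case` column
#'   (0/1), optionally `er_status` (`ERpos` / `ERneg` / `unknown`).
#' @param covar_path optional TSV with header: sample id first, covariate
#'   columns after. `NULL` for no covariates.
#' @return A `CaseControlPanel`: list with `dosages` (matrix), `phenotype`
#'   (data.frame `sample_id`, `case`, `er_status`), `covariates`
#'   (data.frame, possibly 0-column) and `n_dropped` (samples lost in the
#'   join or to missing phenotype).
#' @export
read_case_control <- function(dosage_path, pheno_path, covar_path = NULL) {
  dos <- read_tsv_input(dosage_path)
  ph <- read_tsv_input(pheno_path)
  ids_d <- as.character(dos[[1]])
  ids_p <- as.character(ph[[1]])
  if (anyDuplicated(ids_d) || anyDuplicated(ids_p))
    stop("duplicate sample ids in input tables")
  cov <- NULL
  if (!is.null(covar_path)) {
    cov <- read_tsv_input(covar_path)
    if (anyDuplicated(as.character(cov[[1]])))
      stop("duplicate sample ids in covariate table")
  }
  keep <- intersect(ids_d, ids_p)
  if (!is.null(cov)) keep <- intersect(keep, as.character(cov[[1]]))
  if (!length(keep)) stop("no overlapping samples between inputs")
  ph <- ph[match(keep, ids_p), , drop = FALSE]
  has_pheno <- !is.na(ph$case)
  n_dropped <- (length(ids_d) - length(keep)) + sum(!has_pheno)
  keep <- keep[has_pheno]
  ph <- ph[has_pheno, , drop = FALSE]
  if (n_dropped > 0L)
    pl_log("io", n_dropped, " sample(s) dropped (join or missing phenotype)")
  dosages <- as.matrix(dos[match(keep, ids_d), -1, drop = FALSE])
  rownames(dosages) <- keep
  if (any(dosages < 0 | dosages > 2)) stop("dosages must lie in [0, 2]")
  phenotype <- data.frame(
    sample_id = keep, case = as.integer(ph$case),
    er_status = if ("er_status" %in% names(ph)) as.character(ph$er_status)
                else "unknown",
    stringsAsFactors = FALSE)
  covariates <- if (is.null(cov)) {
    data.frame(row.names = keep)
  } else {
    out <- cov[match(keep, as.character(cov[[1]])), -1, drop = FALSE]
    rownames(out) <- keep
    out
  }
  case_control_panel(dosages, phenotype, covariates, n_dropped = n_dropped)
}

#' Construct a case-control panel
#'
#' @param dosages individual-by-variant matrix with values in \[0, 2\];
#'   row names are sample ids, column names variant ids.
#' @param phenotype data.frame with `sample_id`, `case` (0/1) and
#'   optionally `er_status`, aligned 1:1 with dosage rows.
#' @param covariates data.frame of covariates aligned with dosage rows
#'   (may have zero columns).
#' @param n_dropped samples dropped upstream (bookkeeping).
#' @return An object of class `CaseControlPanel`.
#' @export
case_control_panel <- function(dosages, phenotype,
                               covariates = data.frame(), n_dropped = 0L) {
  dosages <- as.matrix(dosages)
  stopifnot(nrow(dosages) == nrow(phenotype))
  if (!"er_status" %in% names(phenotype)) phenotype$er_status <- "unknown"
  if (nrow(covariates) && nrow(covariates) != nrow(dosages))
    stop("covariate rows must align 1:1 with dosage rows")
  if (any(dosages < 0 | dosages > 2)) stop("dosages must lie in [0, 2]")
  structure(list(dosages = dosages, phenotype = phenotype,
                 covariates = covariates, n_dropped = n_dropped),
            class = "CaseControlPanel")
}

#' @export
print.CaseControlPanel <- function(x, ...) {
  cat(sprintf("CaseControlPanel: %d cases / %d controls x %d variants, %d covariate(s)\n",
              sum(x$phenotype$case == 1), sum(x$phenotype$case == 0),
              ncol(x$dosages), ncol(x$covariates)))
  invisible(x)
}

#' Extract allelic dosages from a VCF
#'
#' Uses the DS field when present, otherwise counts alternate alleles
#' from hard GT calls (0/1/2).
#'
#' @param vcf_path path to a VCF file.
#' @return individual-by-variant dosage matrix.
#' @export
read_dosages_vcf <- function(vcf_path) {
  vcf <- VariantAnnotation::readVcf(vcf_path, genome = "unknown")
  g <- VariantAnnotation::geno(vcf)
  if ("DS" %in% names(g)) {
    ds <- g$DS
    storage.mode(ds) <- "double"
    return(t(ds))
  }
  gt <- g$GT
  if (is.null(gt)) stop("VCF has neither DS nor GT: ", vcf_path)
  dos <- (substr(gt, 1, 1) != "0") + (substr(gt, 3, 3) != "0")
  dos <- matrix(as.numeric(dos), nrow = nrow(gt), dimnames = dimnames(gt))
  t(dos)
}

#' Two-set merge quality control
#'
#' Reproduces the merge-stage filters used when combining two genotyped
#' or imputed variant sets: a variant is retained only if present in both
#' sets with matching alleles, its MAF is at least `maf_min` in both sets,
#' its imputation INFO is at least `info_min` in both sets, and the
#' alternate-allele frequencies of the two sets differ by at most
#' `dfreq_max`.
#'
#' @param set_a,set_b data.frames keyed by `id` with columns `maf`, `info`,
#'   `alt_freq` and optionally `ref`/`alt` for allele checking.
#' @param maf_min minimum minor allele frequency (default 0.006, i.e. 0.6%).
#' @param info_min minimum imputation info score in either set (default 0.5).
#' @param dfreq_max maximum allowed |alt_freq difference| (default 0.15).
#' @return list with `retained` (character ids), and `exclusions`
#'   (data.frame `id`, `reason` with reasons `not_in_both`,
#'   `allele_mismatch`, `maf`, `info`, `dfreq`), and `tally` (table of
#'   exclusion reasons). `retained` + excluded ids partition the union of
#'   input ids.
#' @export
merge_qc <- function(set_a, set_b, maf_min = 0.006, info_min = 0.5,
                     dfreq_max = 0.15) {
  all_ids <- union(set_a$id, set_b$id)
  shared <- intersect(set_a$id, set_b$id)
  a <- set_a[match(shared, set_a$id), , drop = FALSE]
  b <- set_b[match(shared, set_b$id), , drop = FALSE]
  reason <- rep(NA_character_, length(shared))
  if (!is.null(a$ref) && !is.null(b$ref)) {
    mism <- a$ref != b$ref | a$alt != b$alt
    reason[is.na(reason) & mism] <- "allele_mismatch"
  }
  fail_maf <- a$maf < maf_min | b$maf < maf_min
  reason[is.na(reason) & fail_maf] <- "maf"
  fail_info <- (!is.na(a$info) & a$info < info_min) |
               (!is.na(b$info) & b$info < info_min)
  reason[is.na(reason) & fail_info] <- "info"
  fail_df <- abs(a$alt_freq - b$alt_freq) > dfreq_max
  reason[is.na(reason) & fail_df] <- "dfreq"
  retained <- shared[is.na(reason)]
  only_one <- setdiff(all_ids, shared)
  exclusions <- rbind(
    data.frame(id = only_one,
               reason = rep("not_in_both", length(only_one)),
               stringsAsFactors = FALSE),
    data.frame(id = shared[!is.na(reason)], reason = reason[!is.na(reason)],
               stringsAsFactors = FALSE))
  list(retained = retained, exclusions = exclusions,
       tally = table(exclusions$reason))
}
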