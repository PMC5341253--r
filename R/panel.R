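#' Construct a phased haplotype panel
#'
#' A `HaplotypePanel` holds phased binary haplotypes for one population:
#' a haplotype-by-variant 0/1 matrix (2N rows for N diploid samples,
#' 0 = reference allele, 1 = alternate allele) together with per-variant
#' metadata. The alternate-allele frequency is always recomputed from the
#' matrix so the stored `alt_freq` and the column means agree exactly.
#'
#' @param variants data.frame with columns `id`, `chrom`, `pos`, `ref`,
#'   `alt` and optionally `info` (imputation quality). Must be strictly
#'   sorted by `pos` within a chromosome; `id` must be unique.
#' @param matrix integer/numeric matrix of 0/1 alleles, haplotypes in rows,
#'   variants in columns (same order as `variants`).
#' @param population character label for the population.
#' @return An object of class `HaplotypePanel`: a list with elements
#'   `variants` (data.frame including `alt_freq` and `maf`), `matrix`
#'   (with variant ids as column names) and `population`.
#' @export
haplotype_panel <- function(variants, matrix, population = "unknown") {
  stopifnot(is.data.frame(variants),
            all(c("id", "chrom", "pos", "ref", "alt") %in% names(variants)))
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != nrow(variants))
    stop("matrix has ", ncol(matrix), " columns but ", nrow(variants),
         " variants supplied")
  if (anyDuplicated(variants$id))
    stop("duplicate variant ids: ",
         paste(unique(variants$id[duplicated(variants$id)]), collapse = ", "))
  if (!all(matrix %in% c(0, 1)))
    stop("haplotype matrix must be binary (0 = ref, 1 = alt)")
  if (any(variants$pos < 1)) stop("positions must be >= 1")
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    # non-decreasing: ties only arise from split multi-allelic records,
    # which keep distinct ids
    if (is.unsorted(p, strictly = FALSE))
      stop("variants must be sorted by position within chromosome ", ch)
  }
  storage.mode(matrix) <- "integer"
  colnames(matrix) <- variants$id
  variants$alt_freq <- unname(colMeans(matrix))
  variants$maf <- pmin(variants$alt_freq, 1 - variants$alt_freq)
  if (is.null(variants$info))
    variants$info <- rep(NA_real_, nrow(variants))
  structure(list(variants = variants, matrix = matrix,
                 population = population),
            class = "HaplotypePanel")
}

#' @export
print.HaplotypePanel <- function(x, ...) {
  cat(sprintf("HaplotypePanel: %d haplotypes (%d diploid samples) x %d variants [%s]\n",
              nrow(x$matrix), nrow(x$matrix) %/% 2, ncol(x$matrix),
              x$population))
  if (nrow(x$variants)) {
    rng <- range(x$variants$pos)
    cat(sprintf("  chrom %s, pos %d..%d, MAF %.4f..%.4f\n",
                paste(unique(x$variants$chrom), collapse = ","),
                rng[1], rng[2], min(x$variants$maf), max(x$variants$maf)))
  }
  invisible(x)
}

#' Number of haplotypes in a panel
#' @param panel a `HaplotypePanel`.
#' @return integer count of haplotype rows (2 per diploid sample).
#' @export
n_haplotypes <- function(panel) nrow(panel$matrix)

# Column of the haplotype matrix for a variant id, with a clear error.
panel_column <- function(panel, id) {
  j <- match(id, panel$variants$id)
  if (is.na(j)) stop("variant '", id, "' not found in panel")
  panel$matrix[, j]
}

#' Describe a GWAS-discovered variant to follow up
#'
#' @param id variant identifier (must match the catalog id).
#' @param risk_allele `"ref"` or `"alt"`, the reported risk allele.
#' @param phenotype one of `"overall"`, `"ERpos"`, `"ERneg"`.
#' @param discovery_population free-text label of the discovery GWAS
#'   population (used for ancestry-stratified summaries; anything matching
#'   `"african"` case-insensitively is binned as African ancestry).
#' @param reported_direction sign (+1/-1) of the reported effect of the
#'   alternate allele, or `NA` when unknown.
#' @return An object of class `GwasHit`.
#' @export
gwas_hit <- function(id, risk_allele = "alt", phenotype = "overall",
                     discovery_population = "unknown",
                     reported_direction = NA_real_) {
  stopifnot(risk_allele %in% c("ref", "alt"),
            phenotype %in% c("overall", "ERpos", "ERneg"))
  structure(list(id = id, risk_allele = risk_allele, phenotype = phenotype,
                 discovery_population = discovery_population,
                 reported_direction = reported_direction),
            class = "GwasHit")
}

#' @export
print.GwasHit <- function(x, ...) {
  cat(sprintf("GwasHit %s (%s, risk allele: %s, discovered in %s)\n",
              x$id, x$phenotype, x$risk_allele, x$discovery_population))
  invisible(x)
}
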