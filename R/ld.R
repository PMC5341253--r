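#' Pairwise linkage disequilibrium from phased haplotypes
#'
#' Computes the signed disequilibrium coefficient D and the squared
#' correlation r^2 from haplotype counts (Haploview-style): with
#' p11 = freq(1,1), pX = freq(x=1), pY = freq(y=1),
#' D = p11 - pX*pY and r^2 = D^2 / (pX(1-pX) pY(1-pY)).
#' If either locus is monomorphic, r^2 is defined as 0 and flagged so
#' downstream denominators stay well-defined.
#'
#' @param x,y binary haplotype vectors of equal length (>= 2).
#' @return list of class `LDValue`: `r2`, `d`, `n_hap`, `monomorphic`.
#' @export
haplotype_r2 <- function(x, y) {
  if (length(x) != length(y))
    stop("haplotype vectors differ in length (", length(x), " vs ",
         length(y), ")")
  if (length(x) < 2L) stop("need at least 2 haplotypes")
  if (!all(x %in% c(0, 1)) || !all(y %in% c(0, 1)))
    stop("haplotype vectors must be binary")
  # haplotype counts (in double precision: the squared numerator overflows
  # 32-bit integers) keep the statistic exactly symmetric in (x, y)
  n <- as.numeric(length(x))
  sx <- as.numeric(sum(x)); sy <- as.numeric(sum(y))
  sxy <- as.numeric(sum(x * y))
  num <- n * sxy - sx * sy
  d <- num / n^2
  denom_counts <- sx * (n - sx) * sy * (n - sy)
  mono <- denom_counts == 0
  r2 <- if (mono) 0 else min(num * num / denom_counts, 1)
  structure(list(r2 = r2, d = d, n_hap = n, monomorphic = mono),
            class = "LDValue")
}

#' @export
print.LDValue <- function(x, ...) {
  cat(sprintf("LDValue: r2 = %.4f, D = %.4f (n_hap = %d%s)\n", x$r2, x$d,
              x$n_hap, if (x$monomorphic) ", monomorphic" else ""))
  invisible(x)
}

#' LD profile of one variant against a set of variants
#'
#' Vectorized batch form of [haplotype_r2()]: r^2 and D of `target`
#' against every id in `against` within one panel. The target itself,
#' if present in `against`, yields r^2 = 1.
#'
#' @param panel a `HaplotypePanel`.
#' @param target variant id.
#' @param against character vector of variant ids (defaults to the whole
#'   panel).
#' @return data.frame with columns `id`, `r2`, `d`, `n_hap`, `monomorphic`,
#'   one row per id in `against` (same order).
#' @export
ld_profile <- function(panel, target, against = panel$variants$id) {
  missing <- setdiff(c(target, against), panel$variants$id)
  if (length(missing))
    stop("variant id(s) not in panel: ", paste(missing, collapse = ", "))
  t_col <- panel_column(panel, target)
  jj <- match(against, panel$variants$id)
  x <- panel$matrix[, jj, drop = FALSE]
  n <- nrow(x)
  s <- colSums(x)
  st <- sum(t_col)
  num <- n * as.numeric(crossprod(x, t_col)) - s * st
  d <- num / n^2
  denom_counts <- s * (n - s) * st * (n - st)
  mono <- denom_counts == 0
  r2 <- ifelse(mono, 0, pmin(num * num / ifelse(mono, 1, denom_counts), 1))
  data.frame(id = against, r2 = r2, d = d, n_hap = n, monomorphic = mono,
             row.names = NULL, stringsAsFactors = FALSE)
}
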