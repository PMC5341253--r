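#' Select candidate causal variants around a GWAS hit
#'
#' Step one of the preferential LD approach. A catalog variant is a
#' candidate if it (1) lies in the window of `window_radius` bp on each
#' side of the hit (a 1 Mb interval for the default 500 kb radius),
#' (2) was not interrogated by the discovery GWAS (not in `platform`),
#' and (3) under `freq_rule = "strict_rarer"`, has MAF strictly below the
#' hit's MAF in this panel. `freq_rule = "off"` drops the frequency
#' filter, the relaxation appropriate when discovery and follow-up
#' populations differ and allele frequencies shift.
#'
#' @param panel follow-up `HaplotypePanel` (the variant catalog).
#' @param hit a [gwas_hit()]; its id must be present in the panel.
#' @param platform character vector of GWAS-interrogated variant ids.
#' @param window_radius bp on each side of the hit (default 500000).
#' @param freq_rule `"strict_rarer"` (default) or `"off"`.
#' @return An object of class `CandidateSet`: list with `hit`,
#'   `window_radius`, `candidates` (data.frame `id`, `chrom`, `pos`,
#'   `maf`, `r2_to_hit`), `n_catalog_in_window`, `n_platform_in_window`,
#'   and `platform_in_window` (platform ids in the window including the
#'   hit, the denominator set for the preferential LD statistic).
#' @export
select_candidates <- function(panel, hit, platform, window_radius = 500000L,
                              freq_rule = c("strict_rarer", "off")) {
  freq_rule <- match.arg(freq_rule)
  stopifnot(inherits(hit, "GwasHit"))
  j <- match(hit$id, panel$variants$id)
  if (is.na(j)) stop("GWAS hit '", hit$id, "' absent from panel")
  v <- panel$variants
  hit_pos <- v$pos[j]
  hit_chrom <- v$chrom[j]
  hit_maf <- v$maf[j]
  in_window <- v$chrom == hit_chrom &
    v$pos >= hit_pos - window_radius & v$pos <= hit_pos + window_radius
  win <- v[in_window, , drop = FALSE]
  platform_in_window <- union(intersect(platform, win$id), hit$id)
  is_cand <- !(win$id %in% platform) & win$id != hit$id
  if (freq_rule == "strict_rarer") is_cand <- is_cand & win$maf < hit_maf
  cand <- win[is_cand, c("id", "chrom", "pos", "maf"), drop = FALSE]
  rownames(cand) <- NULL
  cand$r2_to_hit <- if (nrow(cand))
    ld_profile(panel, hit$id, cand$id)$r2 else numeric()
  structure(list(hit = hit, window_radius = window_radius,
                 candidates = cand,
                 n_catalog_in_window = nrow(win),
                 n_platform_in_window = length(intersect(platform, win$id)),
                 platform_in_window = platform_in_window),
            class = "CandidateSet")
}

#' @export
print.CandidateSet <- function(x, ...) {
  cat(sprintf("CandidateSet around %s: %d candidate(s) of %d catalog variant(s) in +/-%d bp (%d platform variant(s) in window)\n",
              x$hit$id, nrow(x$candidates), x$n_catalog_in_window,
              x$window_radius, x$n_platform_in_window))
  invisible(x)
}

#' Preferential LD statistic
#'
#' Step two: the fraction of GWAS-interrogated variants in the window that
#' tag the candidate as well as or better than the GWAS hit does,
#' |{v in platform : r2(v, candidate) >= r2(hit, candidate)}| / |platform|.
#' The hit always ties with itself, so the floor is 1/P where P is the
#' platform-in-window count (hit included). Small values mean the hit
#' tags the candidate preferentially, even when the absolute r2 is low.
#'
#' @param panel `HaplotypePanel`.
#' @param candidate candidate variant id (must not be on the platform).
#' @param hit_id GWAS hit id; must be an element of `platform_in_window`.
#' @param platform_in_window ids of GWAS-interrogated variants in the
#'   window, including the hit.
#' @return numeric statistic in \[1/P, 1\].
#' @export
preferential_ld_statistic <- function(panel, candidate, hit_id,
                                      platform_in_window) {
  if (!hit_id %in% platform_in_window)
    stop("hit '", hit_id, "' must be part of the platform set in the window")
  if (candidate %in% platform_in_window)
    stop("candidate '", candidate,
         "' is a platform variant; candidates must be un-interrogated")
  prof <- ld_profile(panel, candidate, platform_in_window)
  r2_hit <- prof$r2[match(hit_id, prof$id)]
  mean(prof$r2 >= r2_hit)
}

#' Permutation test for non-random LD with the hit
#'
#' Step three: tests whether the candidate's observed r2 with the hit
#' exceeds what random placement of its alleles would produce. The null
#' permutes the candidate's allele column across haplotypes, preserving
#' its allele frequency and destroying LD; under that scheme the count of
#' (1,1) haplotypes is hypergeometric, which is sampled directly (one
#' draw per permutation, exactly the column-shuffle distribution).
#' p = (1 + #\{perm : r2_perm >= r2_obs\}) / (1 + n_perm).
#'
#' @param panel `HaplotypePanel`.
#' @param candidate,hit_id variant ids present in the panel.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed; the result is deterministic given the seed.
#' @return list: `p`, `r2_obs`, `n_perm`, `monomorphic` (if the candidate
#'   or hit is monomorphic, p = 1 with the flag set).
#' @export
permutation_test <- function(panel, candidate, hit_id, n_perm = 1000L,
                             seed = NULL) {
  if (n_perm < 100L) stop("n_perm must be at least 100")
  obs <- haplotype_r2(panel_column(panel, candidate),
                      panel_column(panel, hit_id))
  if (obs$monomorphic)
    return(list(p = 1, r2_obs = 0, n_perm = n_perm, monomorphic = TRUE))
  x <- panel_column(panel, candidate)
  h <- panel_column(panel, hit_id)
  n <- length(x)
  k <- sum(x)
  kh <- sum(h)
  m <- as.numeric(with_seed(seed, stats::rhyper(n_perm, kh, n - kh, k)))
  n <- as.numeric(n); k <- as.numeric(k); kh <- as.numeric(kh)
  num <- n * m - k * kh
  r2_perm <- num * num / (k * (n - k) * kh * (n - kh))
  p <- (1 + sum(r2_perm >= obs$r2 - 1e-12)) / (1 + n_perm)
  list(p = p, r2_obs = obs$r2, n_perm = n_perm, monomorphic = FALSE)
}

# In-set percentile rank in (0,1): mid-ranks for ties, (rank - 0.5)/n.
# A single element gets 0.5.
percentile_rank <- function(x) {
  (rank(x, ties.method = "average") - 0.5) / length(x)
}

#' Sorting score combining preferential tagging and conservation
#'
#' Step four: each candidate's score combines two in-set percentile
#' ranks — of the (small is good) preferential LD statistic and of the
#' (large is good) conservation score. Lower combined score = higher
#' priority. Significance of each score is assessed by randomly
#' reassigning the conservation values across candidates `n_perm` times
#' and recomputing; candidates whose score beats `alpha` are flagged as
#' final candidates.
#'
#' @param cset `CandidateSet` whose `candidates` already carry `pl_stat`.
#' @param conservation data.frame `chrom`, `pos`, `score` (as from
#'   [read_conservation()]); positions missing a score are imputed with
#'   the candidate-set median and flagged.
#' @param n_perm permutations for score significance (default 1000).
#' @param seed integer seed.
#' @param combiner `"rank_mean"` (weighted mean of the two percentile
#'   ranks; default) or `"rank_product"` (weighted geometric mean).
#' @param weights length-2 weights for (pl_stat, conservation); must sum
#'   to 1.
#' @param alpha significance level for the score flag (default 0.05).
#' @return the `CandidateSet` with columns `conservation`,
#'   `conservation_imputed`, `sort_score`, `score_p`, `score_sig` filled.
#' @export
sorting_score <- function(cset, conservation, n_perm = 1000L, seed = NULL,
                          combiner = c("rank_mean", "rank_product"),
                          weights = c(0.5, 0.5), alpha = 0.05) {
  combiner <- match.arg(combiner)
  stopifnot(length(weights) == 2, abs(sum(weights) - 1) < 1e-8)
  cand <- cset$candidates
  if (!nrow(cand)) {
    cset$candidates <- cbind(cand, conservation = numeric(),
                             conservation_imputed = logical(),
                             sort_score = numeric(), score_p = numeric(),
                             score_sig = logical())
    return(cset)
  }
  if (is.null(cand$pl_stat))
    stop("candidates lack pl_stat; run preferential_ld_statistic first ",
         "(see score_candidates)")
  key <- paste(cand$chrom, cand$pos)
  cons <- conservation$score[match(key, paste(conservation$chrom,
                                              conservation$pos))]
  imputed <- is.na(cons)
  if (any(imputed)) cons[imputed] <- stats::median(cons, na.rm = TRUE)
  if (all(is.na(cons))) stop("no conservation scores match any candidate")
  pct_pl <- percentile_rank(cand$pl_stat)
  pct_cons <- percentile_rank(-cons)
  combine <- function(a, b) {
    if (combiner == "rank_mean") weights[1] * a + weights[2] * b
    else exp(weights[1] * log(a) + weights[2] * log(b))
  }
  score <- combine(pct_pl, pct_cons)
  n <- length(score)
  exceed <- integer(n)
  with_seed(seed, for (b in seq_len(n_perm)) {
    perm_score <- combine(pct_pl, pct_cons[sample.int(n)])
    exceed <- exceed + (perm_score <= score)
  })
  cand$conservation <- cons
  cand$conservation_imputed <- imputed
  cand$sort_score <- score
  cand$score_p <- (1 + exceed) / (1 + n_perm)
  cand$score_sig <- cand$score_p < alpha
  cset$candidates <- cand
  cset
}

#' Rank prioritized candidates
#'
#' Ranks by ascending sorting score; ties broken by ascending
#' preferential LD statistic, then ascending position. Deterministic and
#' invariant to input row order.
#'
#' @param cset `CandidateSet` with `sort_score` filled.
#' @return the `CandidateSet` with an integer `rank` column (a permutation
#'   of 1..n).
#' @export
rank_candidates <- function(cset) {
  cand <- cset$candidates
  if (!nrow(cand)) {
    cand$rank <- integer()
    cset$candidates <- cand
    return(cset)
  }
  if (is.null(cand$sort_score)) stop("sort_score missing; run sorting_score")
  ord <- order(cand$sort_score, cand$pl_stat, cand$pos)
  cand$rank <- integer(nrow(cand))
  cand$rank[ord] <- seq_len(nrow(cand))
  cset$candidates <- cand
  cset
}

#' Score a candidate set end to end
#'
#' Convenience wrapper running steps two to four of the preferential LD
#' approach on a [select_candidates()] output: computes the preferential
#' LD statistic and the LD permutation test for every candidate, keeps
#' the candidates with non-random LD with the hit (permutation p <
#' `perm_alpha`), then applies [sorting_score()] and [rank_candidates()].
#'
#' @param cset `CandidateSet` from [select_candidates()].
#' @param panel the `HaplotypePanel` the set was selected from.
#' @param conservation data.frame `chrom`, `pos`, `score`.
#' @param n_perm permutations for both the LD test and the score test.
#' @param seed integer seed.
#' @param perm_alpha retention threshold on the LD permutation p
#'   (default 0.05); failing candidates are removed and counted in
#'   `n_filtered_perm`.
#' @param ... passed to [sorting_score()] (`combiner`, `weights`, `alpha`).
#' @return the scored, filtered, ranked `CandidateSet` with element
#'   `n_filtered_perm` added.
#' @export
score_candidates <- function(cset, panel, conservation, n_perm = 1000L,
                             seed = NULL, perm_alpha = 0.05, ...) {
  cand <- cset$candidates
  seeds <- with_seed(seed, sample.int(2147483646L, nrow(cand) + 1L))
  if (nrow(cand)) {
    prof_fun <- function(id) preferential_ld_statistic(
      panel, id, cset$hit$id, cset$platform_in_window)
    cand$pl_stat <- vapply(cand$id, prof_fun, numeric(1))
    cand$perm_p <- vapply(seq_len(nrow(cand)), function(i)
      permutation_test(panel, cand$id[i], cset$hit$id, n_perm = n_perm,
                       seed = seeds[i])$p, numeric(1))
    keep <- cand$perm_p < perm_alpha
    cset$n_filtered_perm <- sum(!keep)
    cand <- cand[keep, , drop = FALSE]
    rownames(cand) <- NULL
  } else {
    cset$n_filtered_perm <- 0L
  }
  cset$candidates <- cand
  cset <- sorting_score(
    cset, conservation, n_perm = n_perm,
    seed = if (is.null(seed)) NULL else seeds[length(seeds)], ...)
  rank_candidates(cset)
}
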