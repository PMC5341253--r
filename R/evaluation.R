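#' Classify replication of a GWAS hit
#'
#' A hit is replicated when its follow-up association has p strictly
#' below `alpha` and the effect direction matches the reported direction.
#' If the reported direction is missing the decision falls back to the
#' p-value alone, with a flag.
#'
#' @param result `AssociationResult` for the hit (same variant and
#'   phenotype).
#' @param hit the [gwas_hit()].
#' @param alpha nominal replication level (default 0.05, strict `<`).
#' @return logical; `attr(, "flag")` is `"no_direction"` when direction
#'   metadata was unavailable.
#' @export
classify_replication <- function(result, hit, alpha = 0.05) {
  stopifnot(result$variant == hit$id, result$phenotype == hit$phenotype)
  sig <- !is.na(result$p) && result$p < alpha
  if (is.na(hit$reported_direction)) {
    out <- sig
    attr(out, "flag") <- "no_direction"
    return(out)
  }
  out <- sig && !is.na(result$direction) &&
    result$direction == hit$reported_direction
  out
}

#' Locus-level comparison of the hit, the best marker, and the best
#' preferential LD candidate
#'
#' Computes, for one locus, the best (minimum-p) marker among all tested
#' catalog variants in the window, the best marker among the preferential
#' LD candidates, and the candidate's rank k among the N tested variants
#' (k = 1 + number of tested variants with p strictly below the best
#' candidate's p, so a candidate tying the global minimum gets k = 1).
#'
#' @param assoc_table data.frame of association results for all tested
#'   catalog variants in the window (columns `variant_id`, `p`).
#' @param candidate_set the scored `CandidateSet` for the locus.
#' @param hit_p the hit's own association p; by default looked up from
#'   `assoc_table`.
#' @return list of class `LocusEvaluation`: `hit_id`, `phenotype`,
#'   `discovery_population`, `hit_p`, `best_overall` (id, p),
#'   `best_pl` (id, p, k, N, r2_to_hit; `NULL` with a flag if no candidate
#'   was tested), `improved` (best candidate p < hit p), `top10` (k <= 10).
#' @export
locus_rank <- function(assoc_table, candidate_set, hit_p = NULL) {
  stopifnot(nrow(assoc_table) > 0)
  tab <- assoc_table[!is.na(assoc_table$p), , drop = FALSE]
  hit <- candidate_set$hit
  if (is.null(hit_p)) {
    i <- match(hit$id, tab$variant_id)
    if (is.na(i)) stop("hit '", hit$id,
                       "' not in assoc_table; pass hit_p explicitly")
    hit_p <- tab$p[i]
  }
  i_best <- which.min(tab$p)
  best_overall <- list(id = tab$variant_id[i_best], p = tab$p[i_best])
  cand_ids <- intersect(candidate_set$candidates$id, tab$variant_id)
  out <- list(hit_id = hit$id, phenotype = hit$phenotype,
              discovery_population = hit$discovery_population,
              hit_p = hit_p, best_overall = best_overall, best_pl = NULL,
              improved = NA, top10 = NA, flag = NA_character_)
  class(out) <- "LocusEvaluation"
  if (!length(cand_ids)) {
    out$flag <- "no_tested_candidates"
    return(out)
  }
  ct <- tab[tab$variant_id %in% cand_ids, , drop = FALSE]
  j <- which.min(ct$p)
  p_pl <- ct$p[j]
  k <- 1L + sum(tab$p < p_pl)
  r2 <- candidate_set$candidates$r2_to_hit[
    match(ct$variant_id[j], candidate_set$candidates$id)]
  out$best_pl <- list(id = ct$variant_id[j], p = p_pl, k = k,
                      N = nrow(tab), r2_to_hit = r2)
  out$improved <- p_pl < hit_p
  out$top10 <- k <= 10L
  out
}

#' @export
print.LocusEvaluation <- function(x, ...) {
  cat(sprintf("LocusEvaluation %s [%s]: hit p = %.3g; best overall %s (p = %.3g)",
              x$hit_id, x$phenotype, x$hit_p, x$best_overall$id,
              x$best_overall$p))
  if (!is.null(x$best_pl))
    cat(sprintf("; best candidate %s (p = %.3g, rank %d/%d)",
                x$best_pl$id, x$best_pl$p, x$best_pl$k, x$best_pl$N))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.LocusEvaluation <- function(x, ...) {
  data.frame(hit_id = x$hit_id, phenotype = x$phenotype,
             discovery_population = x$discovery_population, hit_p = x$hit_p,
             best_overall_id = x$best_overall$id,
             best_overall_p = x$best_overall$p,
             best_pl_id = if (is.null(x$best_pl)) NA_character_
                          else x$best_pl$id,
             best_pl_p = if (is.null(x$best_pl)) NA_real_ else x$best_pl$p,
             rank_k = if (is.null(x$best_pl)) NA_integer_ else x$best_pl$k,
             rank_n = if (is.null(x$best_pl)) NA_integer_ else x$best_pl$N,
             best_pl_r2 = if (is.null(x$best_pl)) NA_real_
                          else x$best_pl$r2_to_hit,
             improved = x$improved, top10 = x$top10,
             stringsAsFactors = FALSE)
}

is_african_label <- function(x) grepl("african", x, ignore.case = TRUE)

#' Summarize preferential LD performance over evaluated loci
#'
#' Computes the headline performance summary: the percentage of loci
#' where the best preferential LD candidate beat the GWAS hit
#' (`pct_improved`, one decimal), the percentage of those improved loci
#' where the candidate ranked in the locus top 10
#' (`pct_top10_among_improved`, whole percent), and optionally
#' ancestry-stratified replication rates from supplied counts.
#'
#' @param evals list of `LocusEvaluation` objects, or a data.frame with
#'   columns `hit_p`, `best_pl_p`, `rank_k` (and optionally `improved`,
#'   `top10`, which are recomputed when absent).
#' @param replication_counts optional data.frame with columns `ancestry`,
#'   `n_tested`, `n_replicated` giving the replication tally by discovery
#'   ancestry; rates are percentages to one decimal.
#' @return list with `n_loci`, `n_improved`, `pct_improved`,
#'   `n_top10_improved`, `pct_top10_among_improved`, and (when counts are
#'   given) `replication` (the counts with a `rate` column plus an
#'   `overall` row).
#' @export
summarize_improvement <- function(evals, replication_counts = NULL) {
  if (is.data.frame(evals)) df <- evals
  else df <- do.call(rbind, lapply(evals, as.data.frame))
  if (is.null(df) || nrow(df) == 0)
    return(list(n_loci = 0L, n_improved = 0L, pct_improved = NA_real_,
                n_top10_improved = 0L,
                pct_top10_among_improved = NA_real_, replication = NULL))
  if (is.null(df$improved)) df$improved <- df$best_pl_p < df$hit_p
  if (is.null(df$top10)) df$top10 <- df$rank_k <= 10L
  n <- nrow(df)
  n_imp <- sum(df$improved, na.rm = TRUE)
  n_top <- sum(df$improved & df$top10, na.rm = TRUE)
  repl <- NULL
  if (!is.null(replication_counts)) {
    rc <- replication_counts
    rc$rate <- round(100 * rc$n_replicated / rc$n_tested, 1)
    overall <- data.frame(ancestry = "all",
                          n_tested = sum(rc$n_tested),
                          n_replicated = sum(rc$n_replicated))
    overall$rate <- round(100 * overall$n_replicated / overall$n_tested, 1)
    repl <- rbind(rc, overall)
  }
  list(n_loci = n, n_improved = n_imp,
       pct_improved = round(100 * n_imp / n, 1),
       n_top10_improved = n_top,
       pct_top10_among_improved = if (n_imp) round(100 * n_top / n_imp)
                                  else NA_real_,
       replication = repl)
}

#' Expected/observed points for a QQ plot of p-values
#'
#' @param pvalues numeric vector of p-values in (0, 1]; zeros are clamped
#'   to the smallest positive double with a warning.
#' @return data.frame `expected`, `observed` (-log10 scale), observed
#'   sorted ascending in p; the expected quantile for rank i of n is
#'   i/(n+1).
#' @export
qq_points <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  if (any(pvalues == 0)) {
    warning("p-value(s) of 0 clamped to the smallest positive double")
    pvalues[pvalues == 0] <- .Machine$double.xmin
  }
  n <- length(pvalues)
  obs <- sort(pvalues)
  data.frame(expected = -log10(seq_len(n) / (n + 1)),
             observed = -log10(obs))
}

#' Published locus-level follow-up summary
#'
#' Loads the bundled published summary of 20 replicated breast cancer
#' GWAS loci evaluated in an African American consortium: for each
#' (hit, phenotype) pair the hit's follow-up p-value and the best
#' preferential LD candidate's p-value and rank among all tested catalog
#' variants in the 500 kb neighborhood.
#'
#' @param canonical_only keep only the canonical 20-locus accounting
#'   (all overall-risk loci plus the two subtype-only loci); `FALSE`
#'   returns every published (hit, phenotype) row.
#' @return data.frame with columns `hit_id`, `phenotype`,
#'   `discovery_population`, `hit_p`, `best_overall_id`, `best_overall_p`,
#'   `best_overall_r2`, `best_pl_id`, `best_pl_p`, `rank_k`, `rank_n`,
#'   `best_pl_r2`, `in_20_locus_set`.
#' @export
published_loci <- function(canonical_only = TRUE) {
  path <- system.file("extdata", "published_locus_summary.tsv",
                      package = "prefld", mustWork = TRUE)
  x <- read_tsv_input(path)
  x$in_20_locus_set <- as.logical(x$in_20_locus_set)
  if (canonical_only) x <- x[x$in_20_locus_set, , drop = FALSE]
  rownames(x) <- NULL
  x
}

#' Published replication counts by discovery ancestry
#'
#' @return data.frame `ancestry`, `n_tested`, `n_replicated` for the
#'   published follow-up of 74 GWAS hits (7 discovered in African-ancestry
#'   populations, 67 elsewhere).
#' @export
published_replication_counts <- function() {
  path <- system.file("extdata", "published_replication_counts.tsv",
                      package = "prefld", mustWork = TRUE)
  read_tsv_input(path)
}
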