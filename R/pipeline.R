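#' Configuration for a follow-up run
#'
#' @param window_radius bp each side of a hit (default 500000).
#' @param freq_rule `"strict_rarer"` or `"off"` (candidate frequency
#'   filter).
#' @param n_perm permutations for the LD and sorting-score tests.
#' @param seed integer seed for all randomized stages.
#' @param replication_alpha nominal replication level (default 0.05).
#' @param family_alpha family-wise level for the study-wide cutoff
#'   (default 0.05).
#' @param perm_alpha retention threshold for the LD permutation filter.
#' @param covariate_alpha covariate screening threshold (default 0.1).
#' @param forced_covariates covariates always included.
#' @param combiner,weights sorting-score combiner settings.
#' @return list of class `RunConfig`.
#' @export
followup_config <- function(window_radius = 500000L,
                            freq_rule = "strict_rarer",
                            n_perm = 1000L, seed = 1L,
                            replication_alpha = 0.05,
                            family_alpha = 0.05,
                            perm_alpha = 0.05,
                            covariate_alpha = 0.1,
                            forced_covariates = character(),
                            combiner = "rank_mean",
                            weights = c(0.5, 0.5)) {
  structure(as.list(environment()), class = "RunConfig")
}

#' Run the full trans-ethnic follow-up workflow
#'
#' For each GWAS hit: test its allelic-dosage association and classify
#' replication (nominal p with consistent direction); for replicated hits
#' only, select candidate causal variants in the window, compute
#' preferential LD statistics, filter by the LD permutation test, rank by
#' the conservation-aware sorting score, test every catalog variant in
#' the window that is present in the case-control panel, and evaluate the
#' locus (best marker vs best candidate). Finally, the study-wide cutoff
#' is derived from the effective number of independent tests over the
#' union of tested variants, and the locus evaluations are summarized.
#' Stage failures abort the affected locus with a logged reason; other
#' loci continue.
#'
#' @param catalog follow-up `HaplotypePanel` (the variant catalog).
#' @param platform character vector of GWAS-interrogated variant ids.
#' @param conservation data.frame `chrom`, `pos`, `score`.
#' @param cc_panel `CaseControlPanel` of the follow-up study.
#' @param hits data.frame manifest with columns `id`, `phenotype`,
#'   `discovery_population`, `risk_allele`, `reported_direction`.
#' @param config a [followup_config()].
#' @param out_dir optional directory; when given, per-stage TSVs and a
#'   JSON-like run report are written there.
#' @return list of class `followup_report`: `loci` (per-hit list with
#'   `replicated`, `candidate_set`, `assoc_table`, `evaluation`, `status`),
#'   `m_eff`, `m_raw`, `cutoff`, `summary`, `covariates_used`, `config`.
#' @export
run_followup <- function(catalog, platform, conservation, cc_panel, hits,
                         config = followup_config(), out_dir = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  loci <- list()
  tested_union <- character()
  evals <- list()
  covs_by_pheno <- list()
  seeds <- with_seed(config$seed, sample.int(2147483646L, nrow(hits)))

  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    hit <- gwas_hit(h$id, risk_allele = h$risk_allele,
                    phenotype = h$phenotype,
                    discovery_population = h$discovery_population,
                    reported_direction = h$reported_direction)
    locus <- list(hit = hit, replicated = FALSE, status = "ok")
    res <- tryCatch({
      if (is.null(covs_by_pheno[[hit$phenotype]]))
        covs_by_pheno[[hit$phenotype]] <- screen_covariates(
          cc_panel, hit$phenotype, alpha = config$covariate_alpha,
          forced_in = config$forced_covariates)
      covs <- covs_by_pheno[[hit$phenotype]]
      hit_assoc <- dosage_logistic(cc_panel, hit$id, hit$phenotype,
                                   covariates = covs)
      locus$hit_assoc <- hit_assoc
      locus$replicated <- isTRUE(as.logical(
        classify_replication(hit_assoc, hit,
                             alpha = config$replication_alpha)))
      pl_log("replicate", hit$id, " [", hit$phenotype, "] p = ",
             signif(hit_assoc$p, 3), ", replicated = ", locus$replicated)
      if (locus$replicated) {
        cset <- select_candidates(catalog, hit, platform,
                                  window_radius = config$window_radius,
                                  freq_rule = config$freq_rule)
        cset <- score_candidates(cset, catalog, conservation,
                                 n_perm = config$n_perm, seed = seeds[i],
                                 perm_alpha = config$perm_alpha,
                                 combiner = config$combiner,
                                 weights = config$weights)
        locus$candidate_set <- cset
        j <- match(hit$id, catalog$variants$id)
        w <- catalog$variants
        in_win <- w$chrom == w$chrom[j] &
          abs(w$pos - w$pos[j]) <= config$window_radius
        tested <- intersect(w$id[in_win], colnames(cc_panel$dosages))
        assoc <- assoc_scan(cc_panel, tested, hit$phenotype,
                            covariates = covs)
        locus$assoc_table <- assoc
        tested_union <- union(tested_union, tested)
        locus$evaluation <- locus_rank(assoc, cset)
        evals[[length(evals) + 1L]] <- locus$evaluation
        pl_log("evaluate", hit$id, ": ", nrow(cset$candidates),
               " candidate(s), ", length(tested), " tested variant(s)")
      }
      locus
    }, error = function(e) {
      locus$status <- conditionMessage(e)
      pl_log("error", hit$id, ": ", locus$status)
      locus
    })
    loci[[paste0(h$id, "_", h$phenotype)]] <- res
  }

  m_eff <- NA_real_
  cutoff <- NA_real_
  if (length(tested_union)) {
    vt <- catalog$variants[catalog$variants$id %in% tested_union,
                           c("id", "chrom")]
    eff <- effective_tests_blocked(cc_panel, vt)
    m_eff <- eff$m_eff
    cutoff <- study_wide_cutoff(config$family_alpha, m_eff)
  }
  summary <- summarize_improvement(evals)

  report <- structure(
    list(loci = loci, n_hits = nrow(hits),
         n_replicated = sum(vapply(loci, `[[`, logical(1), "replicated")),
         m_eff = m_eff, m_raw = length(tested_union), cutoff = cutoff,
         summary = summary, covariates_used = covs_by_pheno,
         config = config),
    class = "followup_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.followup_report <- function(x, ...) {
  cat(sprintf("Follow-up run: %d/%d hit(s) replicated\n", x$n_replicated,
              x$n_hits))
  if (!is.na(x$m_eff))
    cat(sprintf("  %d variant(s) tested, M_eff = %.1f, study-wide cutoff = %.3g\n",
                x$m_raw, x$m_eff, x$cutoff))
  s <- x$summary
  if (s$n_loci > 0)
    cat(sprintf("  improved loci: %d/%d (%.1f%%); top-10 among improved: %d (%s%%)\n",
                s$n_improved, s$n_loci, s$pct_improved, s$n_top10_improved,
                format(s$pct_top10_among_improved)))
  invisible(x)
}

#' Write the standard TSV outputs of a follow-up run
#'
#' Emits, under `out_dir`: `candidates_<hit>_<phenotype>.tsv` (scored and
#' ranked candidates), `assoc_<hit>_<phenotype>.tsv` (window-wide
#' association), `locus_evaluations.tsv`, `run_summary.tsv`, and
#' `qq_points.tsv` over all tested-variant p-values.
#'
#' @param report a `followup_report`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  eval_rows <- list()
  all_p <- numeric()
  for (locus in report$loci) {
    tag <- paste0(locus$hit$id, "_", locus$hit$phenotype)
    if (!is.null(locus$candidate_set)) {
      write_tsv_output(locus$candidate_set$candidates,
                       file.path(out_dir, paste0("candidates_", tag, ".tsv")),
                       comments = sprintf(
                         "candidates for %s; window +/-%d bp; %d catalog / %d platform variants in window",
                         locus$hit$id, locus$candidate_set$window_radius,
                         locus$candidate_set$n_catalog_in_window,
                         locus$candidate_set$n_platform_in_window))
    }
    if (!is.null(locus$assoc_table)) {
      write_tsv_output(locus$assoc_table,
                       file.path(out_dir, paste0("assoc_", tag, ".tsv")),
                       comments = paste0("window association scan for ",
                                         locus$hit$id))
      all_p <- c(all_p, locus$assoc_table$p[!is.na(locus$assoc_table$p)])
    }
    if (!is.null(locus$evaluation))
      eval_rows[[tag]] <- as.data.frame(locus$evaluation)
  }
  if (length(eval_rows))
    write_tsv_output(do.call(rbind, eval_rows),
                     file.path(out_dir, "locus_evaluations.tsv"),
                     comments = "per-locus best-marker comparison")
  s <- report$summary
  write_tsv_output(
    data.frame(n_hits = report$n_hits, n_replicated = report$n_replicated,
               m_raw = report$m_raw, m_eff = report$m_eff,
               cutoff = report$cutoff, n_loci = s$n_loci,
               n_improved = s$n_improved, pct_improved = s$pct_improved,
               pct_top10_among_improved = s$pct_top10_among_improved,
               seed = report$config$seed),
    file.path(out_dir, "run_summary.tsv"),
    comments = "follow-up run summary")
  if (length(all_p))
    write_tsv_output(qq_points(all_p), file.path(out_dir, "qq_points.tsv"),
                     comments = "expected/observed -log10 p over all tested variants")
  invisible(out_dir)
}
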