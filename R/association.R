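# Case indicator for a phenotype contrast. Subtype analyses compare
# subtype cases to all controls; cases of other/unknown subtype are
# excluded (NA).
case_vector <- function(panel, phenotype = c("overall", "ERpos", "ERneg")) {
  phenotype <- match.arg(phenotype)
  ph <- panel$phenotype
  y <- ph$case
  if (phenotype != "overall") {
    y[ph$case == 1 & ph$er_status != phenotype] <- NA_integer_
  }
  y
}

#' Screen candidate covariates with covariate-only models
#'
#' Fits, for each candidate covariate, a logistic model of case status on
#' that covariate alone and keeps the covariates with likelihood-ratio
#' p-value below `alpha` for the requested phenotype. Covariates listed
#' in `forced_in` are always retained. Constant covariates and covariates
#' producing separation are excluded and flagged.
#'
#' @param panel `CaseControlPanel`.
#' @param phenotype `"overall"`, `"ERpos"` or `"ERneg"`.
#' @param alpha inclusion threshold on the covariate-only p (default 0.1).
#' @param candidates covariate column names to consider (default: all).
#' @param forced_in covariates retained regardless of p (e.g. study, age).
#' @return character vector of included covariates, with a `details`
#'   attribute (data.frame `covariate`, `p`, `status`).
#' @export
screen_covariates <- function(panel, phenotype = "overall", alpha = 0.1,
                              candidates = colnames(panel$covariates),
                              forced_in = character()) {
  y <- case_vector(panel, phenotype)
  details <- data.frame(covariate = character(), p = numeric(),
                        status = character(), stringsAsFactors = FALSE)
  included <- character()
  for (cv in candidates) {
    x <- panel$covariates[[cv]]
    if (is.null(x)) stop("covariate '", cv, "' not found")
    ok <- !is.na(y) & !is.na(x)
    status <- "tested"; p <- NA_real_
    if (length(unique(x[ok])) < 2L) {
      status <- "constant"
    } else {
      fit <- suppressWarnings(
        stats::glm(y[ok] ~ x[ok], family = stats::binomial()))
      null_fit <- stats::glm(y[ok] ~ 1, family = stats::binomial())
      sep <- !fit$converged ||
        any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE)
      if (sep) {
        status <- "separation"
      } else {
        p <- stats::anova(null_fit, fit, test = "Chisq")$`Pr(>Chi)`[2]
        if (cv %in% forced_in) {
          status <- "forced_in"
        } else if (!is.na(p) && p < alpha) {
          status <- "included"
        } else {
          status <- "excluded"
        }
      }
    }
    if (cv %in% forced_in && status %in% c("tested", "excluded", "included"))
      status <- "forced_in"
    if (status %in% c("included", "forced_in")) included <- c(included, cv)
    details <- rbind(details, data.frame(covariate = cv, p = p,
                                         status = status,
                                         stringsAsFactors = FALSE))
  }
  attr(included, "details") <- details
  included
}

#' Allelic-dosage logistic regression
#'
#' Fits `logit P(case) ~ dosage + covariates + conditioning dosages` and
#' reports the odds ratio per alternate allele (exp of the dosage
#' coefficient), its Wald p-value, and the effect direction. Conditioning
#' on other variants' dosages implements conditional analysis: a signal
#' that vanishes after conditioning indicates one underlying association.
#'
#' @param panel `CaseControlPanel`.
#' @param variant variant id (column of the dosage matrix).
#' @param phenotype `"overall"`, `"ERpos"` or `"ERneg"`.
#' @param covariates covariate column names to adjust for.
#' @param condition_on variant ids whose dosages are added as covariates.
#' @return list of class `AssociationResult`: `variant`, `phenotype`,
#'   `or_estimate`, `beta`, `se`, `p`, `direction`, `n_cases`,
#'   `n_controls`, `covariates_used`, `conditioned_on`, `converged`,
#'   `flag`. Non-convergence or an aliased (collinear) dosage term gives
#'   `converged = FALSE`, `p = 1` and a flag rather than an error; a
#'   monomorphic dosage is an error.
#' @export
dosage_logistic <- function(panel, variant, phenotype = "overall",
                            covariates = character(),
                            condition_on = character()) {
  ids <- colnames(panel$dosages)
  for (v in c(variant, condition_on))
    if (!v %in% ids) stop("variant '", v, "' not in dosage matrix")
  y <- case_vector(panel, phenotype)
  dos <- panel$dosages[, variant]
  df <- data.frame(y = y, dosage = dos)
  for (cv in covariates) {
    if (is.null(panel$covariates[[cv]]))
      stop("covariate '", cv, "' not found")
    df[[cv]] <- panel$covariates[[cv]]
  }
  for (v in condition_on) df[[paste0("cond_", v)]] <- panel$dosages[, v]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (stats::var(df$dosage) == 0)
    stop("monomorphic dosage for variant '", variant, "'")
  fit <- suppressWarnings(
    stats::glm(y ~ ., data = df, family = stats::binomial()))
  co <- stats::coef(fit)
  res <- list(variant = variant, phenotype = phenotype,
              or_estimate = NA_real_, beta = NA_real_, se = NA_real_,
              p = 1, direction = NA_real_,
              n_cases = sum(df$y == 1), n_controls = sum(df$y == 0),
              covariates_used = covariates, conditioned_on = condition_on,
              converged = FALSE, flag = NA_character_)
  class(res) <- "AssociationResult"
  if (is.na(co["dosage"]) || anyNA(co[grep("^cond_", names(co))])) {
    res$flag <- "degenerate"   # collinear dosage/conditioning term
    return(res)
  }
  if (!fit$converged || abs(co["dosage"]) > 15) {
    res$flag <- "non_convergence"
    return(res)
  }
  sm <- summary(fit)$coefficients
  res$beta <- co[["dosage"]]
  res$se <- sm["dosage", "Std. Error"]
  res$p <- sm["dosage", "Pr(>|z|)"]
  res$or_estimate <- exp(res$beta)
  res$direction <- sign(res$beta)
  res$converged <- TRUE
  res
}

#' @export
print.AssociationResult <- function(x, ...) {
  cat(sprintf("AssociationResult %s [%s]: OR = %.4f, p = %.3g (%d cases / %d controls%s%s)\n",
              x$variant, x$phenotype, x$or_estimate, x$p, x$n_cases,
              x$n_controls,
              if (length(x$conditioned_on))
                paste0(", conditioned on ",
                       paste(x$conditioned_on, collapse = "+")) else "",
              if (!x$converged) paste0(", FLAG: ", x$flag) else ""))
  invisible(x)
}

#' @export
as.data.frame.AssociationResult <- function(x, ...) {
  data.frame(variant_id = x$variant, phenotype = x$phenotype,
             n_cases = x$n_cases, n_controls = x$n_controls,
             or_estimate = x$or_estimate, beta = x$beta, se = x$se,
             p = x$p, direction = x$direction,
             conditioned_on = paste(x$conditioned_on, collapse = ","),
             covariates = paste(x$covariates_used, collapse = ","),
             converged = x$converged, flag = x$flag,
             stringsAsFactors = FALSE)
}

#' Association scan over a set of variants
#'
#' Runs [dosage_logistic()] for each variant and stacks the results.
#' Monomorphic variants are skipped with a flag row (p = NA).
#'
#' @inheritParams dosage_logistic
#' @param variants variant ids to test.
#' @return data.frame, one row per variant.
#' @export
assoc_scan <- function(panel, variants, phenotype = "overall",
                       covariates = character(),
                       condition_on = character()) {
  rows <- lapply(variants, function(v) {
    res <- tryCatch(
      dosage_logistic(panel, v, phenotype, covariates, condition_on),
      error = function(e) NULL)
    if (is.null(res))
      return(data.frame(variant_id = v, phenotype = phenotype,
                        n_cases = NA_integer_, n_controls = NA_integer_,
                        or_estimate = NA_real_, beta = NA_real_,
                        se = NA_real_, p = NA_real_, direction = NA_real_,
                        conditioned_on = paste(condition_on, collapse = ","),
                        covariates = paste(covariates, collapse = ","),
                        converged = FALSE, flag = "monomorphic",
                        stringsAsFactors = FALSE))
    as.data.frame(res)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Effective number of independent tests
#'
#' Eigenvalue-based estimator (Li & Ji style): with eigenvalues
#' lambda_i of the correlation matrix,
#' M_eff = sum_i ( I(lambda_i >= 1) + (lambda_i - floor(lambda_i)) ).
#' The identity matrix gives M, a perfectly correlated block gives 1.
#'
#' @param correlations symmetric correlation matrix with unit diagonal
#'   (e.g. from [dosage_correlation()]).
#' @param round_result `"none"` (default), `"round"` or `"ceiling"`.
#' @return numeric effective test count in \[1, M\].
#' @export
effective_tests <- function(correlations,
                            round_result = c("none", "round", "ceiling")) {
  round_result <- match.arg(round_result)
  correlations <- as.matrix(correlations)
  if (nrow(correlations) != ncol(correlations) ||
      max(abs(correlations - t(correlations))) > 1e-8)
    stop("correlation matrix must be symmetric")
  if (max(abs(diag(correlations) - 1)) > 1e-8)
    stop("correlation matrix must have unit diagonal")
  lam <- eigen(correlations, symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  # snap to integers: floor() is discontinuous there and eigenvalues of
  # exact-correlation blocks land on integers up to rounding error
  near <- abs(lam - round(lam)) < 1e-9
  lam[near] <- round(lam[near])
  meff <- sum((lam >= 1) + (lam - floor(lam)))
  switch(round_result, none = meff, round = round(meff),
         ceiling = ceiling(meff))
}

#' Correlation matrix of dosages
#'
#' Pearson correlation across individuals of the dosage columns for the
#' given variants; monomorphic variants give zero off-diagonals.
#'
#' @param panel `CaseControlPanel`.
#' @param variants variant ids (default all columns).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
dosage_correlation <- function(panel, variants = colnames(panel$dosages)) {
  x <- panel$dosages[, variants, drop = FALSE]
  sds <- apply(x, 2, stats::sd)
  r <- suppressWarnings(stats::cor(x))
  r[is.na(r)] <- 0
  diag(r) <- 1
  r[sds == 0, sds == 0] <- 0
  diag(r) <- 1
  r
}

#' Chromosome-blocked effective number of tests
#'
#' Inter-chromosome dosage correlation is ~0, so the effective test count
#' is computed per chromosome block and summed. This keeps the
#' eigendecomposition tractable for large variant sets.
#'
#' @param panel `CaseControlPanel`.
#' @param variant_table data.frame with `id` and `chrom` for the tested
#'   variants (ids must be dosage columns).
#' @param round_result passed to [effective_tests()] for the final sum.
#' @return list with `m_eff`, `m_raw` and per-block breakdown `blocks`.
#' @export
effective_tests_blocked <- function(panel, variant_table,
                                    round_result = "none") {
  ids <- variant_table$id[variant_table$id %in% colnames(panel$dosages)]
  vt <- variant_table[match(ids, variant_table$id), , drop = FALSE]
  blocks <- lapply(split(vt$id, vt$chrom), function(v)
    effective_tests(dosage_correlation(panel, v)))
  meff <- sum(unlist(blocks))
  if (round_result == "round") meff <- round(meff)
  if (round_result == "ceiling") meff <- ceiling(meff)
  list(m_eff = meff, m_raw = length(ids),
       blocks = data.frame(chrom = names(blocks),
                           m_eff = unlist(blocks), row.names = NULL))
}

#' Study-wide significance cutoff
#'
#' Bonferroni correction at the effective number of independent tests:
#' `alpha / m_eff`.
#'
#' @param alpha family-wise level in (0,1).
#' @param m_eff effective number of independent tests (>= 1).
#' @return the per-test significance threshold.
#' @export
study_wide_cutoff <- function(alpha, m_eff) {
  stopifnot(alpha > 0, alpha < 1, m_eff >= 1)
  alpha / m_eff
}
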