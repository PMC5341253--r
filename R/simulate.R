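#' Configuration of the two-population synthetic world
#'
#' Defaults emulate the regime the follow-up method targets: a common
#' GWAS hit (MAF ~0.45) that tags a rarer causal variant (MAF ~0.08)
#' strongly in the discovery population (r^2 ~0.6) but only weakly in the
#' follow-up population (r^2 ~0.10, inside the 0.05-0.15 band typical of
#' African-ancestry LD with European-discovered tags), a per-allele odds
#' ratio of 1.5, and a 4000 case / 4000 control follow-up study. The
#' follow-up population has the higher founder-mosaic switch rate, giving
#' shorter-range LD.
#'
#' @param n_founders founder haplotypes shared by both populations.
#' @param n_hap_discovery,n_hap_followup haplotypes per population (the
#'   follow-up default, 492, mirrors a 246-individual reference catalog).
#' @param n_variants catalog variants in the region (before planting the
#'   causal variant).
#' @param region_length region size in bp (1 Mb: one full window).
#' @param switch_rate_discovery,switch_rate_followup per-bp mosaic switch
#'   probabilities; followup must be larger (shorter LD).
#' @param causal_maf,hit_maf target minor allele frequencies in the
#'   follow-up population; the causal variant must be rarer than the hit.
#' @param causal_maf_discovery target causal MAF in the discovery
#'   population. Allele frequencies shift between populations, and a
#'   strong discovery tag (r^2 ~0.6) is only attainable when the causal
#'   variant is comparably common there (r^2 between loci with MAFs 0.08
#'   and 0.45 cannot exceed ~0.11).
#' @param target_r2_discovery,target_r2_followup target hit-causal r^2 per
#'   population; followup must be below discovery.
#' @param odds_ratio per-allele odds ratio of the causal variant.
#' @param prevalence baseline population risk used to solve the logistic
#'   intercept.
#' @param n_cases,n_controls case-control quotas.
#' @param platform_fraction fraction of catalog variants interrogated by
#'   the discovery GWAS platform (hit always included, causal never).
#' @param conservation_shape1,conservation_shape2 Beta parameters of the
#'   background conservation score distribution (right-skewed, most sites
#'   unconserved).
#' @param conservation_boost additive score bump at the causal variant.
#' @param retry_cap rejection-sampling retries when planting the causal
#'   variant.
#' @param seed integer master seed; everything downstream derives from it.
#' @return list of class `SimConfig`.
#' @export
sim_config <- function(n_founders = 30L,
                       n_hap_discovery = 500L,
                       n_hap_followup = 492L,
                       n_variants = 300L,
                       region_length = 1000000L,
                       switch_rate_discovery = 2e-06,
                       switch_rate_followup = 8e-06,
                       causal_maf = 0.08,
                       causal_maf_discovery = 0.40,
                       hit_maf = 0.45,
                       target_r2_discovery = 0.6,
                       target_r2_followup = 0.10,
                       odds_ratio = 1.5,
                       prevalence = 0.10,
                       n_cases = 4000L,
                       n_controls = 4000L,
                       platform_fraction = 0.25,
                       conservation_shape1 = 1.5,
                       conservation_shape2 = 15,
                       conservation_boost = 0.6,
                       retry_cap = 1000L,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$causal_maf >= cfg$hit_maf)
    stop("causal_maf must be below hit_maf (strict-rarer filter must retain the causal variant)")
  if (cfg$target_r2_followup >= cfg$target_r2_discovery)
    stop("target_r2_followup must be below target_r2_discovery")
  if (cfg$n_hap_discovery %% 2L || cfg$n_hap_followup %% 2L)
    stop("haplotype counts must be even (diploid samples)")
  structure(cfg, class = "SimConfig")
}

# One founder-mosaic haplotype set: n_hap x M matrix over given founders.
mosaic_haplotypes <- function(founders, pos, n_hap, switch_rate) {
  m <- length(pos)
  nf <- nrow(founders)
  p_switch <- 1 - exp(-switch_rate * diff(pos))
  out <- matrix(0L, nrow = n_hap, ncol = m)
  for (i in seq_len(n_hap)) {
    if (switch_rate == 0) {
      path <- rep(sample.int(nf, 1L), m)
    } else {
      sw <- stats::runif(m - 1L) < p_switch
      segment <- cumsum(c(1L, sw))
      choice <- sample.int(nf, segment[m], replace = TRUE)
      path <- choice[segment]
    }
    out[i, ] <- founders[cbind(path, seq_len(m))]
  }
  out
}

# Bernoulli column correlated with `h` hitting target maf/r2 by rejection.
plant_correlated_column <- function(h, target_maf, target_r2, retry_cap,
                                    maf_tol = 0.03, r2_rel_tol = 0.5) {
  n <- length(h)
  ph <- mean(h)
  pc <- target_maf                      # causal alt allele is the minor one
  d <- sqrt(target_r2 * ph * (1 - ph) * pc * (1 - pc))
  p1 <- min(1, max(0, pc + d / ph))     # P(c=1 | h=1)
  p0 <- min(1, max(0, pc - d / (1 - ph)))
  for (try in seq_len(retry_cap)) {
    c_col <- ifelse(h == 1L, stats::rbinom(n, 1L, p1), stats::rbinom(n, 1L, p0))
    maf <- min(mean(c_col), 1 - mean(c_col))
    r2 <- haplotype_r2(c_col, h)$r2
    ok <- abs(maf - target_maf) <= maf_tol &&
      r2 >= (1 - r2_rel_tol) * target_r2 &&
      r2 <= (1 + r2_rel_tol) * target_r2
    if (ok) return(list(col = as.integer(c_col), maf = maf, r2 = r2))
  }
  stop("retry cap (", retry_cap, ") exceeded while planting the causal ",
       "variant; loosen target MAF/r2 or raise retry_cap")
}

#' Simulate two-population haplotype panels with a planted causal variant
#'
#' Draws a shared founder pool, builds each population's haplotypes as
#' founder mosaics with its own switch rate (higher switch rate = shorter
#' LD), picks the catalog variant closest to the target hit MAF as the
#' GWAS hit, and plants a causal variant near the hit whose realized MAF
#' and hit-causal r^2 approximate the per-population targets (rejection
#' sampling with a retry cap). Also draws the platform subset: a random
#' `platform_fraction` of catalog variants, always including the hit and
#' never the causal variant. Fully reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `discovery` and `followup` (`HaplotypePanel`s sharing
#'   variant ids), `truth` (list of class `TruthRecord`: `causal_id`,
#'   `hit_id`, realized `maf_causal_*`, `maf_hit_*`, `r2_discovery`,
#'   `r2_followup`, `odds_ratio`) and `platform` (character ids).
#' @export
simulate_panels <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  with_seed(config$seed, {
    m <- config$n_variants
    pos <- sort(sample.int(config$region_length, m))
    chrom <- "1"
    freqs <- stats::runif(m, 0.02, 0.5)
    founders <- matrix(stats::rbinom(config$n_founders * m, 1L,
                                     rep(freqs, each = config$n_founders)),
                       nrow = config$n_founders)
    disc <- mosaic_haplotypes(founders, pos, config$n_hap_discovery,
                              config$switch_rate_discovery)
    foll <- mosaic_haplotypes(founders, pos, config$n_hap_followup,
                              config$switch_rate_followup)

    maf_foll <- pmin(colMeans(foll), 1 - colMeans(foll))
    maf_disc <- pmin(colMeans(disc), 1 - colMeans(disc))
    # hit: polymorphic in both populations, near the target MAF, and
    # central enough that the +/-500 kb window covers most of the region
    central <- pos > config$region_length * 0.25 &
      pos < config$region_length * 0.75
    eligible <- central & maf_foll > 0.01 & maf_disc > 0.01
    if (!any(eligible)) stop("no eligible hit variant; increase n_variants")
    j_hit <- which(eligible)[which.min(abs(maf_foll[eligible] -
                                             config$hit_maf))]

    cf <- plant_correlated_column(foll[, j_hit], config$causal_maf,
                                  config$target_r2_followup,
                                  config$retry_cap)
    cd <- plant_correlated_column(disc[, j_hit], config$causal_maf_discovery,
                                  config$target_r2_discovery,
                                  config$retry_cap)

    # place the causal variant at an unused position within 250 kb of the hit
    repeat {
      causal_pos <- pos[j_hit] + sample(c(-1L, 1L), 1L) *
        sample.int(250000L, 1L)
      if (causal_pos >= 1L && causal_pos <= config$region_length &&
          !causal_pos %in% pos) break
    }
    ids <- sprintf("snp_%07d", pos)
    causal_id <- sprintf("snp_%07d", causal_pos)
    hit_id <- ids[j_hit]

    insert_at <- findInterval(causal_pos, pos)
    ord_pos <- append(pos, causal_pos, after = insert_at)
    ord_ids <- append(ids, causal_id, after = insert_at)
    alleles <- c("A", "C", "G", "T")
    refs <- sample(alleles, m + 1L, replace = TRUE)
    alts <- vapply(refs, function(r) sample(setdiff(alleles, r), 1L),
                   character(1))
    vtab <- data.frame(id = ord_ids, chrom = chrom, pos = ord_pos,
                       ref = refs, alt = alts, stringsAsFactors = FALSE)

    bind_causal <- function(hap, causal_col) {
      cbind(hap[, seq_len(insert_at), drop = FALSE], causal_col,
            hap[, setdiff(seq_len(m), seq_len(insert_at)), drop = FALSE])
    }
    discovery <- haplotype_panel(vtab, bind_causal(disc, cd$col),
                                 population = "discovery")
    followup <- haplotype_panel(vtab, bind_causal(foll, cf$col),
                                population = "followup")

    n_plat <- max(1L, round(config$platform_fraction * m))
    platform <- union(hit_id,
                      sample(setdiff(ids, c(hit_id, causal_id)),
                             min(n_plat, m - 1L)))

    truth <- structure(list(causal_id = causal_id, hit_id = hit_id,
                            maf_causal_discovery = cd$maf,
                            maf_causal_followup = cf$maf,
                            maf_hit_discovery = maf_disc[j_hit],
                            maf_hit_followup = maf_foll[j_hit],
                            r2_discovery = cd$r2,
                            r2_followup = cf$r2,
                            odds_ratio = config$odds_ratio),
                       class = "TruthRecord")
    list(discovery = discovery, followup = followup, truth = truth,
         platform = platform)
  })
}

# logistic intercept giving the target prevalence for a dosage distribution
solve_intercept <- function(prevalence, log_or, p_allele) {
  dens <- stats::dbinom(0:2, 2, p_allele)
  f <- function(b0) sum(dens * stats::plogis(b0 + log_or * (0:2))) - prevalence
  stats::uniroot(f, c(-20, 20))$root
}

#' Simulate a retrospective case-control panel from a haplotype panel
#'
#' Forms diploid individuals by pairing haplotypes drawn with replacement
#' from the panel, assigns disease by a logistic model on the causal
#' dosage (intercept solved for the configured baseline prevalence), and
#' samples until the case and control quotas are both met (retrospective
#' ascertainment). Cases get an ER subtype label; two null covariates
#' (study site, age) are attached so covariate screening is exercisable.
#'
#' @param panel `HaplotypePanel` of the study population.
#' @param truth `TruthRecord` naming the causal variant and odds ratio.
#' @param config the [sim_config()] (quotas, prevalence, seed).
#' @param seed optional override of `config$seed`.
#' @return a `CaseControlPanel` with the causal dosage effect planted.
#' @export
simulate_phenotypes <- function(panel, truth, config, seed = config$seed) {
  if (config$n_cases < 1L || config$n_controls < 1L)
    stop("n_cases and n_controls must both be positive")
  j_causal <- match(truth$causal_id, panel$variants$id)
  if (is.na(j_causal)) stop("causal variant not in panel")
  log_or <- log(truth$odds_ratio)
  b0 <- solve_intercept(config$prevalence, log_or,
                        panel$variants$alt_freq[j_causal])
  n_hap <- nrow(panel$matrix)
  with_seed(seed, {
    need <- config$n_cases + config$n_controls
    batch <- max(2000L, need)
    max_batches <- ceiling(40 * need / (batch * min(config$prevalence,
                                                    1 - config$prevalence)))
    cases <- NULL; controls <- NULL
    for (b in seq_len(max_batches)) {
      i1 <- sample.int(n_hap, batch, replace = TRUE)
      i2 <- sample.int(n_hap, batch, replace = TRUE)
      dos_causal <- panel$matrix[cbind(i1, j_causal)] +
        panel$matrix[cbind(i2, j_causal)]
      y <- stats::rbinom(batch, 1L, stats::plogis(b0 + log_or * dos_causal))
      pick_case <- which(y == 1L)
      pick_ctrl <- which(y == 0L)
      take_case <- pick_case[seq_len(min(length(pick_case),
                                         config$n_cases -
                                           NROW(cases)))]
      take_ctrl <- pick_ctrl[seq_len(min(length(pick_ctrl),
                                         config$n_controls -
                                           NROW(controls)))]
      if (length(take_case))
        cases <- rbind(cases, cbind(i1[take_case], i2[take_case]))
      if (length(take_ctrl))
        controls <- rbind(controls, cbind(i1[take_ctrl], i2[take_ctrl]))
      if (NROW(cases) >= config$n_cases &&
          NROW(controls) >= config$n_controls) break
    }
    if (NROW(cases) < config$n_cases || NROW(controls) < config$n_controls)
      stop("case/control quota unreachable at the sampling cap; ",
           "check prevalence and odds_ratio")
    pairs <- rbind(cases, controls)
    case <- c(rep(1L, config$n_cases), rep(0L, config$n_controls))
    dosages <- panel$matrix[pairs[, 1], , drop = FALSE] +
      panel$matrix[pairs[, 2], , drop = FALSE]
    n <- nrow(dosages)
    ids <- sprintf("ind_%05d", seq_len(n))
    rownames(dosages) <- ids
    er <- rep("unknown", n)
    er[case == 1L] <- sample(c("ERpos", "ERneg", "unknown"),
                             sum(case), replace = TRUE,
                             prob = c(0.54, 0.30, 0.16))
    phenotype <- data.frame(sample_id = ids, case = case, er_status = er,
                            stringsAsFactors = FALSE)
    covariates <- data.frame(
      study = sample(c("siteA", "siteB"), n, replace = TRUE),
      age = round(stats::rnorm(n, 56, 9)),
      row.names = ids, stringsAsFactors = FALSE)
    case_control_panel(dosages, phenotype, covariates)
  })
}

#' Simulate conservation scores enriched at the causal variant
#'
#' Background scores are Beta-distributed (right-skewed, like genome-wide
#' conservation tracks where most sites score low); the causal position
#' receives an additive boost.
#'
#' @param panel `HaplotypePanel` providing positions.
#' @param truth `TruthRecord` naming the causal variant.
#' @param config the [sim_config()].
#' @param seed optional override of `config$seed`.
#' @return data.frame `chrom`, `pos`, `score` for every panel variant.
#' @export
simulate_conservation <- function(panel, truth, config,
                                  seed = config$seed) {
  v <- panel$variants
  with_seed(seed, {
    score <- stats::rbeta(nrow(v), config$conservation_shape1,
                          config$conservation_shape2)
    score[v$id == truth$causal_id] <-
      score[v$id == truth$causal_id] + config$conservation_boost
    data.frame(chrom = v$chrom, pos = v$pos, score = score,
               stringsAsFactors = FALSE)
  })
}
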