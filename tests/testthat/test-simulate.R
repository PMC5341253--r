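# Scaled-down configuration for generator-mechanics tests (the full-size
# stated regime is exercised in the acceptance suite).
small_cfg <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(n_hap_discovery = 200L, n_hap_followup = 200L, n_variants = 120L,
         n_cases = 400L, n_controls = 400L, seed = seed),
    list(...))
  do.call(sim_config, args)
}

test_that("panels are reproducible from the seed and respect targets", {
  cfg <- small_cfg(seed = 101L)
  a <- simulate_panels(cfg)
  b <- simulate_panels(cfg)
  expect_identical(a$followup$matrix, b$followup$matrix)
  expect_identical(a$discovery$matrix, b$discovery$matrix)
  expect_identical(a$truth, b$truth)
  expect_identical(a$platform, b$platform)

  tr <- a$truth
  expect_lt(tr$maf_causal_followup, tr$maf_hit_followup)  # strict-rarer holds
  expect_lt(tr$r2_followup, tr$r2_discovery)
  expect_gt(tr$r2_discovery, 0.3)
  expect_lt(tr$r2_followup, 0.2)
  # the causal variant is never on the platform; the hit always is
  expect_false(tr$causal_id %in% a$platform)
  expect_true(tr$hit_id %in% a$platform)
  # both panels share the variant catalog
  expect_identical(a$followup$variants$id, a$discovery$variants$id)
})

test_that("zero switch rate copies founders verbatim", {
  cfg <- small_cfg(seed = 5L, switch_rate_discovery = 0,
                   switch_rate_followup = 1e-6)
  sim <- simulate_panels(cfg)
  # drop the planted causal column: founder copies concern the catalog
  j <- match(sim$truth$causal_id, sim$discovery$variants$id)
  hap <- sim$discovery$matrix[, -j]
  n_distinct <- nrow(unique(hap))
  expect_lte(n_distinct, cfg$n_founders)
})

test_that("a higher switch rate shortens LD", {
  wins <- vapply(1:20, function(i) {
    cfg <- small_cfg(seed = 200L + i)
    sim <- simulate_panels(cfg)
    mean_r2_within <- function(panel, max_dist = 50000L) {
      v <- panel$variants
      idx <- which(v$pos < max(v$pos))
      pairs <- cbind(idx[-length(idx)], idx[-1])
      near <- pairs[v$pos[pairs[, 2]] - v$pos[pairs[, 1]] <= max_dist, ,
                    drop = FALSE]
      mean(vapply(seq_len(nrow(near)), function(k)
        haplotype_r2(panel$matrix[, near[k, 1]],
                     panel$matrix[, near[k, 2]])$r2, numeric(1)))
    }
    mean_r2_within(sim$discovery) > mean_r2_within(sim$followup)
  }, logical(1))
  # one-sided sign test at the 1% level: >= 15 of 20 successes
  expect_gte(sum(wins), 15L)
})

test_that("phenotype simulation plants the configured dosage effect", {
  cfg <- small_cfg(seed = 7L)
  sim <- simulate_panels(cfg)
  cc <- simulate_phenotypes(sim$followup, sim$truth, cfg)
  expect_equal(sum(cc$phenotype$case == 1), cfg$n_cases)
  expect_equal(sum(cc$phenotype$case == 0), cfg$n_controls)
  expect_equal(ncol(cc$dosages), ncol(sim$followup$matrix))

  # null model: OR = 1 leaves the causal dosage balanced across groups
  cfg0 <- small_cfg(seed = 8L, odds_ratio = 1)
  sim0 <- simulate_panels(cfg0)
  cc0 <- simulate_phenotypes(sim0$followup, sim0$truth, cfg0)
  d <- cc0$dosages[, sim0$truth$causal_id]
  diff <- abs(mean(d[cc0$phenotype$case == 1]) -
                mean(d[cc0$phenotype$case == 0]))
  se <- sqrt(var(d) * (1 / cfg0$n_cases + 1 / cfg0$n_controls))
  expect_lt(diff, 4 * se)

  bad <- small_cfg(seed = 9L); bad$n_cases <- 0L
  expect_error(simulate_phenotypes(sim$followup, sim$truth, bad),
               "positive")
})

test_that("the fitted odds ratio recovers the planted effect", {
  cfg <- small_cfg(seed = 11L, n_cases = 1000L, n_controls = 1000L)
  sim <- simulate_panels(cfg)
  covered <- vapply(1:120, function(i) {
    cc <- simulate_phenotypes(sim$followup, sim$truth, cfg, seed = 500L + i)
    res <- dosage_logistic(cc, sim$truth$causal_id)
    ci <- res$beta + c(-1.96, 1.96) * res$se
    log(cfg$odds_ratio) >= ci[1] && log(cfg$odds_ratio) <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("conservation scores are boosted only at the causal variant", {
  cfg <- small_cfg(seed = 12L)
  sim <- simulate_panels(cfg)
  cons <- simulate_conservation(sim$followup, sim$truth, cfg)
  expect_equal(nrow(cons), nrow(sim$followup$variants))
  j <- match(sim$followup$variants$pos[
    sim$followup$variants$id == sim$truth$causal_id], cons$pos)
  expect_equal(cons$score[j], max(cons$score))  # boost 0.6 dominates Beta bg
  cons2 <- simulate_conservation(sim$followup, sim$truth, cfg)
  expect_identical(cons, cons2)

  cfg0 <- small_cfg(seed = 12L, conservation_boost = 0)
  cons0 <- simulate_conservation(sim$followup, sim$truth, cfg0)
  expect_lt(cons0$score[j], 1)  # plain background draw
})
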