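# Toy catalog: 7 variants on one chromosome, hit at pos 100 with MAF 0.4.
# v2 (pos 200) and v3 (pos 300) are rarer off-platform variants; v4/v5 are
# platform variants; v6 (pos 600) is off-platform but more common than the
# hit; v7 (pos 5000) is outside the +/-1000 bp window.
toy_selection_panel <- function() {
  n <- 20L
  mat <- cbind(col_with_ones(n, 1:8),    # hit, maf 0.4
               col_with_ones(n, 1:2),    # v2, maf 0.1
               col_with_ones(n, 1:4),    # v3, maf 0.2
               col_with_ones(n, 1:6),    # v4 platform
               col_with_ones(n, 3:4),    # v5 platform
               col_with_ones(n, 1:9),    # v6, maf 0.45 > hit
               col_with_ones(n, 5:6))    # v7 outside window
  make_panel(mat, pos = c(100L, 200L, 300L, 400L, 500L, 600L, 5000L),
             ids = c("hit", "v2", "v3", "v4", "v5", "v6", "v7"))
}

test_that("select_candidates applies the window, platform and rarity filters", {
  panel <- toy_selection_panel()
  hit <- gwas_hit("hit")
  platform <- c("hit", "v4", "v5")
  cset <- select_candidates(panel, hit, platform, window_radius = 1000L)
  expect_setequal(cset$candidates$id, c("v2", "v3"))
  expect_equal(cset$n_catalog_in_window, 6L)
  expect_equal(cset$n_platform_in_window, 3L)
  # relaxation of the rarity rule admits the more common v6
  off <- select_candidates(panel, hit, platform, window_radius = 1000L,
                           freq_rule = "off")
  expect_setequal(off$candidates$id, c("v2", "v3", "v6"))
  # degenerate window holds only the (on-platform) hit
  zero <- select_candidates(panel, hit, platform, window_radius = 0L)
  expect_equal(nrow(zero$candidates), 0L)
  expect_error(select_candidates(panel, gwas_hit("nope"), platform),
               "absent")
})

test_that("candidate sets never contain platform variants and record r2", {
  panel <- toy_selection_panel()
  cset <- select_candidates(panel, gwas_hit("hit"), c("hit", "v4", "v5"),
                            window_radius = 1000L)
  expect_length(intersect(cset$candidates$id, c("hit", "v4", "v5")), 0L)
  direct <- ld_profile(panel, "hit", cset$candidates$id)
  expect_equal(cset$candidates$r2_to_hit, direct$r2)
})

test_that("preferential LD statistic counts platform variants tagging as well as the hit", {
  n <- 20L
  hit_col <- rep(c(1L, 0L), 10)
  cand_col <- hit_col                       # r2 = 1 with the hit
  set.seed(5)
  others <- replicate(9, rbinom(n, 1, 0.4)) # independent, r2 < 1
  mat <- cbind(hit_col, cand_col, others)
  panel <- make_panel(mat, ids = c("hit", "cand", sprintf("p%02d", 1:9)))
  platform <- c("hit", sprintf("p%02d", 1:9))
  # only the hit ties r2 >= 1: statistic at the floor 1/10
  expect_equal(
    preferential_ld_statistic(panel, "cand", "hit", platform), 0.1)

  # r2(hit, cand) = 0: every platform variant ties at >= 0
  ortho <- c(rep(1L, 10), rep(0L, 10))      # orthogonal to alternating hit
  panel2 <- make_panel(cbind(hit_col, ortho, others),
                       ids = c("hit", "cand", sprintf("p%02d", 1:9)))
  expect_equal(haplotype_r2(hit_col, ortho)$r2, 0)
  expect_equal(
    preferential_ld_statistic(panel2, "cand", "hit", platform), 1)

  expect_error(
    preferential_ld_statistic(panel, "p01", "hit", platform),
    "platform")
  expect_error(
    preferential_ld_statistic(panel, "cand", "hit", sprintf("p%02d", 1:9)),
    "hit")
})

test_that("preferential LD statistic matches a brute-force loop", {
  set.seed(11)
  n <- 20L
  mat <- matrix(rbinom(n * 7, 1, 0.35), nrow = n)
  panel <- make_panel(mat, ids = c("hit", "cand", sprintf("p%02d", 1:5)))
  platform <- c("hit", sprintf("p%02d", 1:5))
  # oracle: explicit loop over platform variants with cor()^2 as the
  # independent r2 route
  r2_vs_cand <- vapply(platform, function(v) {
    x <- panel$matrix[, v]; y <- panel$matrix[, "cand"]
    if (var(x) == 0 || var(y) == 0) 0 else cor(x, y)^2
  }, numeric(1))
  oracle <- mean(r2_vs_cand >= r2_vs_cand["hit"])
  expect_equal(
    preferential_ld_statistic(panel, "cand", "hit", platform), oracle)
  stat <- preferential_ld_statistic(panel, "cand", "hit", platform)
  expect_gte(stat, 1 / length(platform))
  expect_lte(stat, 1)
})

test_that("permutation test attains the add-one floor in perfect LD and is deterministic", {
  col <- rep(c(1L, 0L), 50)                 # MAF 0.5, 100 haplotypes
  panel <- make_panel(cbind(col, col), ids = c("hit", "cand"))
  res <- permutation_test(panel, "cand", "hit", n_perm = 500L, seed = 1L)
  expect_equal(res$p, 1 / 501)
  res2 <- permutation_test(panel, "cand", "hit", n_perm = 500L, seed = 1L)
  expect_identical(res, res2)
  res3 <- permutation_test(panel, "cand", "hit", n_perm = 500L, seed = 2L)
  expect_equal(res3$p, res$p)               # floor regardless of seed
  expect_error(permutation_test(panel, "cand", "hit", n_perm = 50L),
               "at least 100")
})

test_that("permutation test flags monomorphic candidates", {
  col <- rep(c(1L, 0L), 10)
  panel <- make_panel(cbind(col, rep(0L, 20)), ids = c("hit", "cand"))
  res <- permutation_test(panel, "cand", "hit", n_perm = 200L, seed = 1L)
  expect_equal(res$p, 1)
  expect_true(res$monomorphic)
})

test_that("hypergeometric null equals an explicit column-shuffle null", {
  set.seed(21)
  n <- 200L
  h <- rbinom(n, 1, 0.35)
  x <- rbinom(n, 1, 0.2)
  # explicit shuffle route
  shuffle_r2 <- replicate(4000, haplotype_r2(sample(x), h)$r2)
  # hypergeometric route (as used internally), on the same count arithmetic
  k <- sum(x); kh <- sum(h)
  m <- rhyper(4000, kh, n - kh, k)
  num <- n * m - k * kh
  hyper_r2 <- num * num / (k * (n - k) * kh * (n - kh))
  grid <- sort(unique(c(shuffle_r2, hyper_r2)))
  gap <- max(abs(ecdf(shuffle_r2)(grid) - ecdf(hyper_r2)(grid)))
  expect_lt(gap, 0.05)
})

test_that("sorting score combines percentile ranks of tagging and conservation", {
  # single candidate: both percentile ranks degenerate to 0.5
  set.seed(8)
  n <- 40L
  mat <- cbind(rbinom(n, 1, 0.4), rbinom(n, 1, 0.1))
  panel <- make_panel(mat, ids = c("hit", "cand"))
  cset <- select_candidates(panel, gwas_hit("hit"), "hit",
                            window_radius = 1000L, freq_rule = "off")
  cset$candidates$pl_stat <- 0.5
  cons <- data.frame(chrom = "1", pos = panel$variants$pos,
                     score = c(0.1, 0.9))
  scored <- sorting_score(cset, cons, n_perm = 200L, seed = 1L)
  expect_equal(scored$candidates$sort_score, 0.5)

  # ten candidates: match an explicit counting oracle for mid-rank
  # percentiles, (#smaller + 0.5*#ties-with-others + 0.5)/n
  pl <- c(0.05, 0.10, 0.10, 0.20, 0.30, 0.35, 0.40, 0.50, 0.60, 0.70)
  cs <- c(0.90, 0.20, 0.80, 0.10, 0.50, 0.50, 0.30, 0.05, 0.60, 0.02)
  pct_oracle <- function(x) vapply(seq_along(x), function(i)
    (sum(x < x[i]) + 0.5 * sum(x == x[i] & seq_along(x) != i) + 0.5) /
      length(x), numeric(1))
  expected <- 0.5 * pct_oracle(pl) + 0.5 * pct_oracle(-cs)

  set.seed(31)
  m <- 11L
  mat <- matrix(rbinom(40 * m, 1, 0.3), nrow = 40)
  mat[, 1] <- rbinom(40, 1, 0.45)
  panel <- make_panel(mat, ids = c("hit", sprintf("c%02d", 1:10)))
  cset <- select_candidates(panel, gwas_hit("hit"), "hit",
                            window_radius = 5000L, freq_rule = "off")
  cset$candidates <- cset$candidates[match(sprintf("c%02d", 1:10),
                                           cset$candidates$id), ]
  cset$candidates$pl_stat <- pl
  cons <- data.frame(chrom = "1",
                     pos = cset$candidates$pos, score = cs)
  scored <- sorting_score(cset, cons, n_perm = 200L, seed = 2L)
  expect_equal(scored$candidates$sort_score, expected, tolerance = 1e-12)

  # a candidate dominating on both components gets the better score
  two <- cset
  two$candidates <- two$candidates[1:2, ]
  two$candidates$pl_stat <- c(0.1, 0.9)
  cons2 <- data.frame(chrom = "1", pos = two$candidates$pos,
                      score = c(0.9, 0.1))
  s2 <- sorting_score(two, cons2, n_perm = 200L, seed = 3L)
  expect_lt(s2$candidates$sort_score[1], s2$candidates$sort_score[2])

  # missing conservation is imputed with the in-set median and flagged
  cons3 <- cons[-4, ]
  s3 <- sorting_score(cset, cons3, n_perm = 200L, seed = 4L)
  expect_true(s3$candidates$conservation_imputed[4])
  expect_equal(s3$candidates$conservation[4], median(cs[-4]))
})

test_that("rank_candidates is deterministic with documented tie-breaks", {
  cset <- structure(list(
    hit = gwas_hit("hit"), window_radius = 1000L,
    candidates = data.frame(
      id = c("a", "b", "c", "d"), chrom = "1",
      pos = c(400L, 300L, 200L, 100L),
      maf = 0.1, r2_to_hit = 0.1,
      pl_stat = c(0.2, 0.1, 0.1, 0.1),
      sort_score = c(0.5, 0.25, 0.25, 0.25),
      stringsAsFactors = FALSE),
    n_catalog_in_window = 5L, n_platform_in_window = 1L,
    platform_in_window = "hit"), class = "CandidateSet")
  ranked <- rank_candidates(cset)
  # ties on score and pl_stat: lower position first
  expect_equal(ranked$candidates$rank, c(4L, 3L, 2L, 1L))
  expect_setequal(ranked$candidates$rank, 1:4)
  # order invariance
  rev_set <- cset
  rev_set$candidates <- cset$candidates[4:1, ]
  ranked_rev <- rank_candidates(rev_set)
  expect_equal(
    ranked_rev$candidates$rank[match(ranked$candidates$id,
                                     ranked_rev$candidates$id)],
    ranked$candidates$rank)
})

test_that("pl_stat is non-increasing in the hit-candidate r2", {
  # raising r2(hit, candidate) while platform r2s stay fixed can only
  # shrink the count of platform variants tagging at least as well
  set.seed(13)
  n <- 60L
  h <- rbinom(n, 1, 0.5)
  others <- replicate(6, rbinom(n, 1, 0.3))
  weak <- rbinom(n, 1, 0.15)              # ~independent of hit
  strong <- h; strong[1:3] <- 1 - strong[1:3]  # high r2 with hit
  ids <- c("hit", sprintf("p%d", 1:6), "weak", "strong")
  panel <- make_panel(cbind(h, others, weak, strong), ids = ids)
  platform <- c("hit", sprintf("p%d", 1:6))
  s_weak <- preferential_ld_statistic(panel, "weak", "hit", platform)
  s_strong <- preferential_ld_statistic(panel, "strong", "hit", platform)
  expect_lte(s_strong, s_weak)
})
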