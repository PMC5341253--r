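test_that("covariate screening keeps informative covariates and drops constants", {
  set.seed(15)
  n <- 2000L
  study <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-0.5 + 1.0 * study))   # true log-OR 1.0
  dosages <- matrix(rbinom(n, 2, 0.3), ncol = 1,
                    dimnames = list(NULL, "v1"))
  panel <- make_cc_panel(dosages, y,
                         covariates = data.frame(
                           study = study,
                           flat = rep(1, n),
                           noise = rnorm(n)))
  inc <- screen_covariates(panel, "overall", alpha = 0.1)
  expect_true("study" %in% inc)
  details <- attr(inc, "details")
  expect_equal(details$status[details$covariate == "flat"], "constant")
  # forced-in covariates are retained regardless of their p-value
  inc2 <- screen_covariates(panel, "overall", alpha = 1e-12,
                            forced_in = "study")
  expect_true("study" %in% inc2)
})

test_that("a strong covariate is included in essentially every replicate", {
  set.seed(16)
  n <- 2000L
  hits <- vapply(1:40, function(i) {
    x <- rbinom(n, 1, 0.5)
    y <- rbinom(n, 1, plogis(-0.5 + 1.0 * x))
    panel <- make_cc_panel(matrix(rbinom(n, 2, 0.3), ncol = 1,
                                  dimnames = list(NULL, "v1")),
                           y, covariates = data.frame(x = x))
    "x" %in% screen_covariates(panel, "overall", alpha = 0.1)
  }, logical(1))
  expect_gt(mean(hits), 0.95)
})

test_that("null covariates are included at about the screening level", {
  set.seed(17)
  n <- 500L
  hits <- vapply(1:500, function(i) {
    x <- rnorm(n)
    y <- rbinom(n, 1, 0.5)
    panel <- make_cc_panel(matrix(rbinom(n, 2, 0.3), ncol = 1,
                                  dimnames = list(NULL, "v1")),
                           y, covariates = data.frame(x = x))
    "x" %in% screen_covariates(panel, "overall", alpha = 0.1)
  }, logical(1))
  # binomial(500, 0.1): mean within ~4 sd of 0.1
  expect_gt(mean(hits), 0.046)
  expect_lt(mean(hits), 0.154)
})

test_that("dosage logistic regression reduces to the 2x2 odds ratio", {
  # {0,2}-coded dosages: 30/100 case carriers, 20/100 control carriers.
  # The allelic OR squared equals the carrier-table OR (30*80)/(70*20).
  dos <- matrix(c(rep(2, 30), rep(0, 70), rep(2, 20), rep(0, 80)),
                ncol = 1, dimnames = list(NULL, "v1"))
  y <- c(rep(1L, 100), rep(0L, 100))
  panel <- make_cc_panel(dos, y)
  res <- dosage_logistic(panel, "v1")
  expect_true(res$converged)
  expect_equal(res$or_estimate^2, (30 * 80) / (70 * 20), tolerance = 1e-6)
  expect_equal(res$direction, 1)
  expect_equal(res$n_cases, 100L)
  expect_equal(res$n_controls, 100L)
})

test_that("conditioning removes a shared signal; self-conditioning is degenerate", {
  set.seed(19)
  n <- 3000L
  g <- rbinom(n, 2, 0.3)
  # near-perfect proxy of g (r2 ~ 0.98)
  proxy <- g
  flip <- sample(n, 30)
  proxy[flip] <- pmin(2, pmax(0, proxy[flip] + sample(c(-1, 1), 30,
                                                      replace = TRUE)))
  y <- rbinom(n, 1, plogis(-0.5 + 0.4 * g))
  dos <- cbind(v1 = g, v2 = proxy)
  panel <- make_cc_panel(dos, y)
  marg <- dosage_logistic(panel, "v2")
  expect_lt(marg$p, 1e-6)
  cond <- dosage_logistic(panel, "v2", condition_on = "v1")
  expect_gt(cond$p, 0.05)

  self <- dosage_logistic(panel, "v1", condition_on = "v1")
  expect_false(self$converged)
  expect_equal(self$flag, "degenerate")
  expect_equal(self$p, 1)

  panel2 <- make_cc_panel(matrix(1, nrow = 10, ncol = 1,
                                 dimnames = list(NULL, "v1")),
                          rep(c(0L, 1L), 5))
  expect_error(dosage_logistic(panel2, "v1"), "monomorphic")
})

test_that("effective_tests matches eigenvalue limits and the 3x3 hand case", {
  expect_equal(effective_tests(diag(7)), 7)
  ones <- matrix(1, 5, 5)
  expect_equal(effective_tests(ones), 1)
  # 3x3 with off-diagonal 0.5: eigenvalues 2, 0.5, 0.5 ->
  # (1 + 0) + (0 + 0.5) + (0 + 0.5) = 2
  r <- matrix(0.5, 3, 3); diag(r) <- 1
  expect_equal(effective_tests(r), 2)
  expect_error(effective_tests(matrix(c(1, 0.4, 0.2, 1), 2, 2)),
               "symmetric")
  expect_equal(effective_tests(r, round_result = "ceiling"), 2)
})

test_that("m_eff is permutation-invariant and duplication adds less than one test", {
  set.seed(23)
  x <- matrix(rnorm(200 * 6), ncol = 6)
  x[, 2] <- x[, 1] + rnorm(200, sd = 0.4)
  r <- cor(x)
  m <- effective_tests(r)
  perm <- sample(6)
  expect_equal(effective_tests(r[perm, perm]), m, tolerance = 1e-9)
  xd <- cbind(x, x[, 3])
  rd <- cor(xd)
  expect_lt(effective_tests(rd), m + 1)
  expect_gte(effective_tests(rd), 1)
})

test_that("blocked m_eff sums per-chromosome estimates", {
  set.seed(29)
  n <- 300L
  dos <- cbind(a1 = rbinom(n, 2, 0.3), a2 = rbinom(n, 2, 0.4),
               b1 = rbinom(n, 2, 0.2))
  panel <- make_cc_panel(dos, rbinom(n, 1, 0.5))
  vt <- data.frame(id = c("a1", "a2", "b1"), chrom = c("1", "1", "2"),
                   stringsAsFactors = FALSE)
  blocked <- effective_tests_blocked(panel, vt)
  direct <- effective_tests(dosage_correlation(panel, c("a1", "a2"))) +
    effective_tests(dosage_correlation(panel, "b1"))
  expect_equal(blocked$m_eff, direct)
  expect_equal(blocked$m_raw, 3L)
})

test_that("study-wide cutoff is alpha over m_eff", {
  expect_equal(study_wide_cutoff(0.05, 1), 0.05)
  expect_equal(study_wide_cutoff(0.05, 50), 1e-3)
  expect_error(study_wide_cutoff(1.2, 10))
})

test_that("ER-subtype contrasts use subtype cases against all controls", {
  dos <- matrix(rep(c(0, 1, 2), length.out = 12), ncol = 1,
                dimnames = list(NULL, "v1"))
  er <- c("ERpos", "ERpos", "ERneg", "unknown",
          rep("unknown", 8))
  case <- c(1L, 1L, 1L, 1L, rep(0L, 8))
  panel <- make_cc_panel(dos, case, er_status = er)
  y <- prefld:::case_vector(panel, "ERpos")
  expect_equal(sum(y == 1, na.rm = TRUE), 2L)   # only ER+ cases
  expect_equal(sum(y == 0, na.rm = TRUE), 8L)   # all controls retained
  expect_equal(sum(is.na(y)), 2L)               # other-subtype cases out
})
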