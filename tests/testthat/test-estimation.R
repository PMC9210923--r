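# Frozen arithmetic for the m = 2000, S = 100, Vbar = 10, P = 20 worked
# case: pi0 = 1900/1990, fdr = pi0 * 10 / 100,
# sigma^2 = 1900/200000 + 1990/400000 = 0.014475.

test_that("pi0 estimator matches direct arithmetic and its edge cases", {
  expect_equal(estimate_pi0(2000, 100, 10), 1900 / 1990)
  expect_equal(estimate_pi0(50, 7, 7), 1)      # S = Vbar
  expect_equal(estimate_pi0(50, 50, 3), 0)     # S = m
  expect_equal(estimate_pi0(100, 90, 95), 1)   # truncated from above
  expect_error(estimate_pi0(100, 10, 100), "smaller than m")
})

test_that("FDR point estimate is pi0-scaled ratio with cap and S=0 guard", {
  pi0 <- estimate_pi0(2000, 100, 10)
  expect_equal(mv_fdr_point(2000, 100, 10, pi0), pi0 * 10 / 100)
  expect_equal(mv_fdr_point(100, 5, 5, 1), 1)
  expect_equal(mv_fdr_point(100, 5, 5 * 3, 1), 1)  # capped
  expect_equal(mv_fdr_point(100, 5, 5 * 3, 1, cap_at_one = FALSE), 3)
  expect_equal(mv_fdr_point(100, 5, 0, 1), 0)
  expect_true(is.na(mv_fdr_point(100, 0, 2, 1)))
})

test_that("se_log_fdr reproduces the two-term delta-method decomposition", {
  se <- se_log_fdr(2000, 100, 10, var_counts = NA, n_perm = 20, c1 = 1)
  expect_equal(se^2, 0.014475)
  expect_equal(se, 0.1203121, tolerance = 1e-6)

  # S = m: the observed-count term vanishes
  se_full <- se_log_fdr(2000, 2000, 10, var_counts = NA, n_perm = 20, c1 = 1)
  expect_equal(se_full^2, 1990 / 400000)

  # doubling P halves the permutation-term contribution
  se40 <- se_log_fdr(2000, 100, 10, var_counts = NA, n_perm = 40, c1 = 1)
  expect_equal(se40^2 - 0.0095, (0.014475 - 0.0095) / 2)

  # c1 estimated from dispersion, floored at 1
  se_under <- se_log_fdr(2000, 100, 10, var_counts = 0.01, n_perm = 20)
  expect_equal(se_under, se)  # under-dispersed counts floored to binomial
  se_over <- se_log_fdr(2000, 100, 10, var_counts = 2 * 10 * (1 - 10 / 2000),
                        n_perm = 20)
  expect_equal(se_over^2, 0.0095 + 2 * 1990 / 400000)

  expect_error(se_log_fdr(2000, 0, 10, NA, 20, 1), "S > 0")
})

test_that("log-normal interval brackets the estimate and widens with cl", {
  ci <- fdr_confint(0.0954774, 0.1203121, cl = 0.95)
  expect_equal(ci$ci_lower, 0.0754207, tolerance = 1e-5)
  expect_equal(ci$ci_upper, 0.1208682, tolerance = 1e-5)

  # multiplicative symmetry: lo * hi = fdr^2
  set.seed(8)
  f <- runif(20, 0.01, 1.5); s <- runif(20, 0.05, 2)
  ci <- fdr_confint(f, s, 0.9)
  expect_equal(ci$ci_lower * ci$ci_upper, f^2)

  # strictly monotone width in cl, for every row
  w <- sapply(c(0.5, 0.8, 0.9, 0.95, 0.99), function(cl) {
    ci <- fdr_confint(f, s, cl); ci$ci_upper - ci$ci_lower
  })
  expect_true(all(apply(w, 1, function(x) all(diff(x) > 0))))

  # se -> 0 collapses the interval onto the point estimate
  ci0 <- fdr_confint(0.3, 1e-12)
  expect_equal(ci0$ci_lower, 0.3, tolerance = 1e-9)
  expect_equal(ci0$ci_upper, 0.3, tolerance = 1e-9)

  expect_error(fdr_confint(0.2, 0.1, cl = 1.2), "cl")
})

test_that("Wald p-value is the normal CDF of log(fdr)/se", {
  expect_equal(wald_pvalue(1, 0.37), 0.5)
  expect_equal(wald_pvalue(exp(-1.6448536 * 0.21), 0.21), 0.05,
               tolerance = 1e-6)
  # capped estimates (fdr > 1 truncated to 1 upstream) give exactly 0.5
  expect_equal(wald_pvalue(pmin(1.8, 1), 0.5), 0.5)
  # p < 0.5 iff fdr < 1
  set.seed(9)
  f <- runif(50, 0.01, 2); s <- runif(50, 0.1, 1)
  p <- wald_pvalue(pmin(f, 1), s)
  expect_equal(p < 0.5, f < 1)
  expect_true(all(p > 0 & p <= 1))
})
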