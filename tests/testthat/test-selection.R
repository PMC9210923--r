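test_that("step-up selection reproduces hand-enumerated cases", {
  expect_equal(bh_select(rep(1, 10), 0.05)$R, 0)
  sel <- bh_select(c(0.001, 0.002, 0.02, 0.3, 0.9), 0.05)
  expect_equal(sel$R, 3)
  expect_equal(sel$alpha_star, 3 * 0.05 / 5)
  expect_equal(sel$selected, c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(bh_select(0.049, 0.05)$R, 1)  # single test = plain alpha test
  expect_equal(bh_select(0.051, 0.05)$R, 0)
  # NA rows (undefined thresholds) are excluded from |T|
  sel_na <- bh_select(c(0.049, NA), 0.05)
  expect_equal(sel_na$n_tests, 1)
  expect_equal(sel_na$selected, c(TRUE, FALSE))
})

test_that("step-up selection matches exhaustive enumeration on random vectors", {
  set.seed(101)
  for (i in 1:1000) {
    n <- sample(1:41, 1)
    p <- runif(n)^sample(1:3, 1)  # skewed toward small values sometimes
    alpha <- sample(c(0.01, 0.05, 0.1), 1)
    sel <- bh_select(p, alpha)
    expect_identical(sel$R, as.integer(bh_brute(p, alpha)))
    expect_identical(sum(sel$selected), as.integer(sel$R))
  }
})

test_that("selection is monotone in alpha", {
  set.seed(55)
  for (i in 1:50) {
    p <- runif(41)^2
    s1 <- bh_select(p, 0.02)$selected
    s2 <- bh_select(p, 0.10)$selected
    expect_true(all(s2[s1]))  # alpha = 0.02 set contained in alpha = 0.10 set
  }
})

make_selected_table <- function(seed = 3, m = 500) {
  fx <- toy_fixture(seed = seed, m = m, n_signal = 40)
  fdr_table(fx$pvals, fx$perms, threshold_grid(1, 5, 0.25))
}

test_that("FCR adjustment widens selected intervals by alpha* = R alpha / |T|", {
  tab <- fdr_select(make_selected_table())
  R <- attr(tab, "R")
  expect_gt(R, 0)
  expect_equal(attr(tab, "alpha_star"),
               R * 0.05 / sum(!is.na(tab$wald_p)))

  sel <- tab$selected_by
  # adjusted interval exists iff selected
  expect_true(all(!is.na(tab$adj_ci_lower[sel])))
  expect_true(all(is.na(tab$adj_ci_lower[!sel])))
  # never narrower than the unadjusted interval; strictly wider when R < |T|
  wid_adj <- (tab$adj_ci_upper - tab$adj_ci_lower)[sel]
  wid_raw <- (tab$ci_upper - tab$ci_lower)[sel]
  if (R < sum(!is.na(tab$wald_p))) {
    expect_true(all(wid_adj > wid_raw))
  } else {
    expect_equal(wid_adj, wid_raw)
  }

  # hand-check the adjusted bounds against the quantile formula
  zs <- qnorm(1 - attr(tab, "alpha_star") / 2)
  expect_equal(tab$adj_ci_upper[sel],
               exp(log(tab$fdr[sel]) + zs * tab$se_log[sel]))
})

test_that("R = |T| makes the adjusted interval equal the unadjusted one", {
  thr <- c(0.05, 0.01)
  obs <- c(300L, 250L)
  perm <- rbind(c(4L, 1L), c(6L, 2L), c(5L, 1L))
  tab <- fdr_table_counts(obs, perm, m = 1000, thresholds = thr)
  tab <- fcr_adjust(tab, alpha = 0.05)
  expect_equal(attr(tab, "R"), 2L)
  expect_equal(attr(tab, "alpha_star"), 0.05)
  expect_equal(tab$adj_ci_lower, tab$ci_lower)
  expect_equal(tab$adj_ci_upper, tab$ci_upper)
})

test_that("no selection returns the table unchanged apart from flags", {
  fx <- toy_fixture(seed = 8, n_signal = 0)
  tab <- fdr_table(fx$pvals, fx$perms, threshold_grid(1, 3, 0.5))
  adj <- fcr_adjust(tab, alpha = 0.05)
  expect_equal(attr(adj, "R"), 0L)
  expect_false(any(adj$selected_by))
  expect_true(all(is.na(adj$adj_ci_lower)))
})

test_that("alpha* quantile matches the R = 1, |T| = 41 worked example", {
  astar <- 1 * 0.05 / 41
  expect_equal(astar, 0.0012195, tolerance = 1e-4)
  expect_equal(qnorm(1 - astar / 2), 3.237, tolerance = 1e-3)
})

test_that("UCB and M.2 selectors equal brute-force filters", {
  tab <- fdr_select(make_selected_table(seed = 14))
  expect_equal(select_ucb(tab),
               !is.na(tab$ci_upper) & tab$ci_upper < 1 & tab$defined)
  expect_equal(select_point(tab, 0.2),
               !is.na(tab$fdr) & tab$fdr < 0.2 & tab$defined)
  # strict inequalities at the boundary
  fake <- tab
  fake$ci_upper[1] <- 1
  fake$fdr[2] <- 0.2
  expect_false(select_ucb(fake)[1])
  expect_false(select_point(fake, 0.2)[2])
})

test_that("capped-at-one rows are never BY-selected at alpha = 0.05", {
  fx <- toy_fixture(seed = 33, n_signal = 30)
  tab <- fdr_select(fdr_table(fx$pvals, fx$perms, threshold_grid(1, 5, 0.25)))
  at_one <- tab$defined & tab$fdr == 1
  expect_false(any(tab$selected_by[at_one]))
  expect_false(any(tab$selected_ucb[at_one]))
})
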