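test_that("true-FDR oracle is identically 1 under the global null", {
  sp <- scenario_spec("E")
  oc <- true_fdr_curve(sp)
  expect_equal(oc$true_fdr, rep(1, length(sp$thresholds)))
})

test_that("true-FDR oracle decreases with stringency and is MC-stable", {
  sp <- scenario_spec("D", thresholds = threshold_grid(2, 5, 0.5))
  oc1 <- true_fdr_curve(sp, n_mc = 600, seed = 11)
  oc2 <- true_fdr_curve(sp, n_mc = 1200, seed = 12)
  # loose thresholds admit mostly false discoveries; strict ones fewer
  expect_gt(oc1$true_fdr[1], oc1$true_fdr[nrow(oc1)] - 3 * oc1$mc_se[1])
  expect_gt(oc1$true_fdr[1], 0.5)
  # doubling n_mc moves each estimate by < 3 combined MC SEs
  se <- sqrt(oc1$mc_se^2 + oc2$mc_se^2)
  ok <- !is.na(oc1$true_fdr) & !is.na(oc2$true_fdr) & oc1$n_pos > 30
  expect_true(all(abs(oc1$true_fdr - oc2$true_fdr)[ok] < 3 * se[ok] + 1e-9))
})

test_that("replicates are deterministic given a seed and score coverage", {
  sp <- scenario_spec("A", thresholds = threshold_grid(2, 4, 0.25))
  truth <- rep(0.5, length(sp$thresholds))
  r1 <- run_replicate(sp, seed = 99, true_fdr = truth)
  r2 <- run_replicate(sp, seed = 99, true_fdr = truth)
  expect_identical(r1$table, r2$table)
  expect_identical(r1$q, r2$q)
  expect_true(all(r1$F <= r1$S))
  expect_true(all(r1$q >= 0 & r1$q <= 1))
})

test_that("Q is zero when nothing is selected", {
  sp <- scenario_spec("E", thresholds = threshold_grid(2, 3, 0.5))
  # find a replicate with no selections under the global null (common)
  for (s in 1:20) {
    r <- run_replicate(sp, seed = 1000 + s, true_fdr = rep(1, 3))
    if (all(r$n_selected == 0)) break
  }
  expect_equal(unname(r$q), c(0, 0, 0))
  expect_false(any(r$any_ub))
})

test_that("UCB-selected intervals always miss under the global null", {
  sp <- scenario_spec("E")
  found <- FALSE
  for (s in 1:60) {
    r <- run_replicate(sp, seed = 2000 + s, true_fdr = rep(1, 41))
    if (r$n_selected["ucb"] > 0) {
      expect_equal(unname(r$q["ucb"]), 1)
      expect_true(r$any_ub["ucb"])
      found <- TRUE
      break
    }
  }
  expect_true(found)  # ~22% of replicates select, 60 tries suffice
})

test_that("experiment summaries are reproducible and internally consistent", {
  sp <- scenario_spec("E")
  e1 <- run_coverage_experiment(sp, n_rep = 60, seed = 17)
  e2 <- run_coverage_experiment(sp, n_rep = 60, seed = 17)
  expect_identical(e1$summary, e2$summary)
  expect_identical(e1$intervals, e2$intervals)

  # global-null identity: every UCB selection misses, so the mean Q equals
  # the any-selection fraction exactly, i.e. coverage = 1 - that fraction
  s <- e1$summary
  expect_identical(s$mean_q[s$method == "UCB"],
                   s$frac_any_ub[s$method == "UCB"])

  td <- tidy(e1)
  expect_equal(td$scenario, rep("E", 3))
  expect_equal(glance(e1)$n_rep, 60)
})

test_that("a high-signal variant recovers the oracle FDR at mid-grid", {
  sp <- scenario_spec("custom", n_nonnull_blocks = 10, effect = 0.5,
                      thresholds = threshold_grid(2, 4, 0.5))
  oc <- true_fdr_curve(sp, n_mc = 1500, seed = 21)
  mid <- 3  # -log10 t = 3.0
  set.seed(22)
  n_rep <- 60
  est <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    r <- run_replicate(sp, true_fdr = oc)
    est[i] <- r$table$fdr[mid]
  }
  mc_se <- sd(est) / sqrt(n_rep)
  expect_lt(abs(mean(est) - oc$true_fdr[mid]),
            3 * sqrt(mc_se^2 + oc$mc_se[mid]^2))
})

test_that("conditional coverage partitions the selected intervals", {
  sp <- scenario_spec("D")
  ex <- run_coverage_experiment(sp, n_rep = 80, seed = 23, n_mc_oracle = 800)
  cc <- conditional_coverage(ex)
  # per-bin counts sum to the number of pooled intervals inside [0, 0.5]
  iv <- ex$intervals
  in_range <- iv$true_fdr >= 0 & iv$true_fdr <= 0.5
  expect_equal(sum(cc$n_intervals), sum(in_range))
  # empty bins are NA, not zero coverage
  expect_true(all(is.na(cc$coverage[cc$n_intervals == 0])))
  expect_true(all(cc$coverage[cc$n_intervals > 0] >= 0 &
                    cc$coverage[cc$n_intervals > 0] <= 1))
})
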