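# One simulated analysis reduced to its sufficient statistics: observed
# rejection counts S, true-null rejection counts F (known from the design),
# and the P x |T| permutation count matrix. Consumes the current RNG stream.
replicate_counts <- function(spec, with_perms = TRUE) {
  dat <- simulate_dataset(spec)
  n <- spec$n
  Xc <- scale(dat$X, scale = FALSE)
  Yc <- scale(dat$Y, scale = FALSE)
  xs <- sqrt(colSums(Xc^2))
  p <- as.vector(pv_kernel(Xc, Yc, xs, n))
  thr <- spec$thresholds
  S <- count_kernel(p, thr)
  F_ <- count_kernel(p[spec$null_pairs], thr)
  perm_counts <- NULL
  if (with_perms) {
    perm_counts <- matrix(0L, spec$n_perm, length(thr))
    for (b in seq_len(spec$n_perm)) {
      pp <- as.vector(pv_kernel(Xc, Yc[sample.int(n), , drop = FALSE], xs, n))
      perm_counts[b, ] <- count_kernel(pp, thr)
    }
  }
  list(S = S, F = F_, perm_counts = perm_counts)
}

#' Monte-Carlo oracle for the true pFDR along the threshold grid
#'
#' Estimates \eqn{E[F/S \mid S > 0]} per threshold by simulating many
#' independent replicates of the scenario and averaging the realized false
#' discovery proportion over those with at least one rejection. `F` is
#' known exactly in simulation: the rejections among the truly null
#' predictor-outcome pairs of the design. Under the global null (scenario
#' E) every discovery is false, so the curve is identically 1 and no
#' simulation is run.
#'
#' @param spec A [scenario_spec()].
#' @param n_mc Number of Monte-Carlo replicates (>= 10000 recommended).
#' @param seed Optional seed for the oracle's own RNG stream.
#'
#' @return A tibble with `threshold`, `neg_log10_t`, `true_fdr` (`NA`
#'   where no replicate produced a rejection), `n_pos` (replicates with
#'   `S > 0`), and `mc_se` (Monte-Carlo standard error of `true_fdr`).
#' @export
true_fdr_curve <- function(spec, n_mc = 10000, seed = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  thr <- spec$thresholds
  nt <- length(thr)
  if (spec$n_nonnull_blocks == 0) {
    return(tibble::tibble(threshold = thr, neg_log10_t = -log10(thr),
                          true_fdr = 1, n_pos = NA_integer_, mc_se = 0))
  }
  if (!is.null(seed)) set.seed(seed)
  s1 <- s2 <- numeric(nt)
  npos <- integer(nt)
  for (i in seq_len(n_mc)) {
    rc <- replicate_counts(spec, with_perms = FALSE)
    pos <- rc$S > 0
    fdp <- rc$F[pos] / rc$S[pos]
    s1[pos] <- s1[pos] + fdp
    s2[pos] <- s2[pos] + fdp^2
    npos[pos] <- npos[pos] + 1L
  }
  mu <- ifelse(npos > 0, s1 / npos, NA_real_)
  vv <- ifelse(npos > 1, (s2 - npos * mu^2) / (npos - 1), NA_real_)
  tibble::tibble(threshold = thr, neg_log10_t = -log10(thr),
                 true_fdr = mu, n_pos = npos,
                 mc_se = sqrt(pmax(vv, 0) / pmax(npos, 1)))
}

# Per-method coverage accounting for one replicate's selected intervals.
method_q <- function(selected, lo, hi, truth) {
  idx <- which(selected & !is.na(truth))
  if (length(idx) == 0) {
    return(list(q = 0, any_ub = FALSE, idx = integer(0), miss = logical(0)))
  }
  miss <- truth[idx] < lo[idx] | truth[idx] > hi[idx]
  list(q = mean(miss), any_ub = any(hi[idx] < 1), idx = idx, miss = miss)
}

#' Run one full replicate analysis of a simulation scenario
#'
#' Simulates a dataset, computes the 2000 marginal p-values, runs `n_perm`
#' shared-row permutation analyses, builds the [fdr_table()] over the
#' scenario grid, applies the three selection rules, and — when a true-FDR
#' curve is supplied — scores each method's selected intervals: an
#' interval covers iff `lower <= true FDR <= upper`, with the BH/FCR
#' method judged on its adjusted interval and the UCB/M.2 comparators on
#' the unadjusted one. `Q` is the proportion of selected intervals not
#' covering (0 when nothing is selected).
#'
#' @inheritParams true_fdr_curve
#' @param seed Optional seed; a fixed seed makes the replicate
#'   bit-reproducible.
#' @param true_fdr Optional per-threshold true pFDR (vector aligned with
#'   the grid, or the tibble from [true_fdr_curve()]).
#'
#' @return A list of class `fdr_replicate` with `table` (the selected
#'   `fdr_table`), `S`, `F`, and per-method `q`, `any_ub`, `n_selected`.
#' @export
run_replicate <- function(spec, seed = NULL, true_fdr = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.data.frame(true_fdr)) true_fdr <- true_fdr$true_fdr
  rc <- replicate_counts(spec)
  tab <- fdr_table_counts(rc$S, rc$perm_counts, m = spec$m,
                          thresholds = spec$thresholds, cl = spec$cl)
  tab <- fdr_select(tab, alpha = spec$alpha, m2_cut = spec$m2_cut)
  out <- list(table = tab, S = rc$S, F = rc$F)
  if (!is.null(true_fdr)) {
    stopifnot(length(true_fdr) == nrow(tab))
    sc <- list(
      by = method_q(tab$selected_by, tab$adj_ci_lower, tab$adj_ci_upper,
                    true_fdr),
      ucb = method_q(tab$selected_ucb, tab$ci_lower, tab$ci_upper, true_fdr),
      m2 = method_q(tab$selected_m2, tab$ci_lower, tab$ci_upper, true_fdr)
    )
    out$q <- vapply(sc, `[[`, 0, "q")
    out$any_ub <- vapply(sc, `[[`, TRUE, "any_ub")
    out$n_selected <- vapply(sc, function(s) length(s$idx), 0L)
    out$scored <- sc
  }
  structure(out, class = "fdr_replicate")
}

#' Coverage experiment: FCR of selected intervals over many replicates
#'
#' Repeats [run_replicate()] `n_rep` times and aggregates, per selection
#' method, the mean of `Q` (the FCR estimate), its complement `coverage =
#' 1 - mean(Q)`, and the fraction of replicates in which at least one
#' selected interval had (method-appropriate) upper bound below 1 — under
#' the global null that fraction is exactly the probability of wrongly
#' asserting that true discoveries exist.
#'
#' Each replicate runs on its own derived seed, so results are
#' reproducible from the master seed and independent of evaluation order.
#'
#' @inheritParams run_replicate
#' @param n_rep Number of replicate studies.
#' @param seed Master seed.
#' @param n_mc_oracle Replicates for the internal [true_fdr_curve()] call
#'   when `true_fdr` is not supplied.
#' @param keep_intervals Keep a per-interval record (needed for
#'   [conditional_coverage()]).
#'
#' @return An object of class `fdr_coverage`: list with `summary` (tibble:
#'   method, mean_q, coverage, frac_any_ub, mean_selected), `q` (tibble of
#'   per-replicate Q values), `intervals` (per-selected-interval tibble),
#'   `true_fdr` (the oracle curve used), `spec`, `n_rep`, `seed`.
#' @export
run_coverage_experiment <- function(spec, n_rep = 2000, seed = 1,
                                    true_fdr = NULL, n_mc_oracle = 10000,
                                    keep_intervals = TRUE) {
  stopifnot(inherits(spec, "scenario_spec"), n_rep >= 1)
  set.seed(seed)
  oracle_seed <- sample.int(.Machine$integer.max - 1, 1)
  rep_seeds <- sample.int(.Machine$integer.max - 1, n_rep)
  if (is.null(true_fdr)) {
    true_fdr <- true_fdr_curve(spec, n_mc = n_mc_oracle, seed = oracle_seed)
  }
  truth <- if (is.data.frame(true_fdr)) true_fdr$true_fdr else true_fdr

  methods <- c("by", "ucb", "m2")
  qmat <- matrix(NA_real_, n_rep, 3, dimnames = list(NULL, methods))
  anymat <- matrix(FALSE, n_rep, 3, dimnames = list(NULL, methods))
  nsel <- matrix(0L, n_rep, 3, dimnames = list(NULL, methods))
  ivals <- if (keep_intervals) vector("list", n_rep) else NULL

  for (i in seq_len(n_rep)) {
    rep_i <- run_replicate(spec, seed = rep_seeds[i], true_fdr = truth)
    qmat[i, ] <- rep_i$q[methods]
    anymat[i, ] <- rep_i$any_ub[methods]
    nsel[i, ] <- rep_i$n_selected[methods]
    if (keep_intervals && sum(rep_i$n_selected) > 0) {
      tab <- rep_i$table
      ivals[[i]] <- purrr::map_dfr(methods, function(mth) {
        s <- rep_i$scored[[mth]]
        if (length(s$idx) == 0) return(NULL)
        lo <- if (mth == "by") tab$adj_ci_lower else tab$ci_lower
        hi <- if (mth == "by") tab$adj_ci_upper else tab$ci_upper
        tibble::tibble(replicate = i, method = mth,
                       neg_log10_t = tab$neg_log10_t[s$idx],
                       fdr = tab$fdr[s$idx],
                       ci_lower = lo[s$idx], ci_upper = hi[s$idx],
                       true_fdr = truth[s$idx], covered = !s$miss)
      })
    }
  }

  summary <- tibble::tibble(
    method = c("BY", "UCB", "M.2"),
    mean_q = colMeans(qmat)[c("by", "ucb", "m2")],
    coverage = 1 - colMeans(qmat)[c("by", "ucb", "m2")],
    frac_any_ub = colMeans(anymat)[c("by", "ucb", "m2")],
    mean_selected = colMeans(nsel)[c("by", "ucb", "m2")],
    mc_se = apply(qmat, 2, stats::sd)[c("by", "ucb", "m2")] / sqrt(n_rep)
  )
  structure(list(
    summary = summary,
    q = tibble::as_tibble(cbind(replicate = seq_len(n_rep),
                                as.data.frame(qmat))),
    any_ub = tibble::as_tibble(cbind(replicate = seq_len(n_rep),
                                     as.data.frame(anymat))),
    intervals = if (keep_intervals) dplyr::bind_rows(ivals) else NULL,
    true_fdr = if (is.data.frame(true_fdr)) true_fdr else
      tibble::tibble(threshold = spec$thresholds,
                     neg_log10_t = -log10(spec$thresholds),
                     true_fdr = truth),
    spec = spec, n_rep = n_rep, seed = seed
  ), class = "fdr_coverage")
}

#' @export
print.fdr_coverage <- function(x, ...) {
  cat("Coverage experiment — scenario", x$spec$scenario,
      "|", x$n_rep, "replicates,", x$spec$n_perm, "permutations each\n")
  print(x$summary)
  invisible(x)
}

#' @describeIn run_coverage_experiment Per-method coverage summary as a
#'   tibble (one row per selection method, with the scenario label).
#' @param x An `fdr_coverage` object.
#' @param ... Unused.
#' @method tidy fdr_coverage
#' @export
tidy.fdr_coverage <- function(x, ...) {
  dplyr::mutate(x$summary, scenario = x$spec$scenario, .before = 1)
}

#' @describeIn run_coverage_experiment One-row design summary.
#' @method glance fdr_coverage
#' @export
glance.fdr_coverage <- function(x, ...) {
  tibble::tibble(scenario = x$spec$scenario, n_rep = x$n_rep,
                 n_perm = x$spec$n_perm, m = x$spec$m,
                 n_thresholds = length(x$spec$thresholds),
                 alpha = x$spec$alpha, cl = x$spec$cl, seed = x$seed)
}

#' Conditional coverage of selected intervals, binned by true FDR
#'
#' Pools the per-interval records of one or more coverage experiments and
#' computes, per selection method and per bin of the true FDR, the
#' proportion of selected intervals that covered. Conditional coverage is
#' a harsher lens than FCR: it conditions on selection, so a method can
#' control FCR overall yet dip badly in the region where its selection
#' rule and the truth disagree.
#'
#' @param x An `fdr_coverage` object, a list of them, or a tibble of
#'   per-interval records with columns `method`, `true_fdr`, `covered`.
#' @param breaks Bin edges on the true-FDR axis (default 10 bins over
#'   \[0, 0.5\]).
#'
#' @return A tibble with `method`, `bin` (factor), `bin_mid`, `coverage`
#'   (`NA` for empty bins), and `n_intervals`.
#' @export
conditional_coverage <- function(x, breaks = seq(0, 0.5, by = 0.05)) {
  if (inherits(x, "fdr_coverage")) x <- list(x)
  iv <- if (is.data.frame(x)) x else {
    dplyr::bind_rows(purrr::map(x, function(e) {
      if (is.null(e$intervals)) {
        stop("experiment was run with keep_intervals = FALSE", call. = FALSE)
      }
      e$intervals
    }))
  }
  stopifnot(all(c("method", "true_fdr", "covered") %in% names(iv)))
  mids <- (utils::head(breaks, -1) + utils::tail(breaks, -1)) / 2
  iv |>
    dplyr::filter(.data$true_fdr >= min(breaks),
                  .data$true_fdr <= max(breaks)) |>
    dplyr::mutate(bin = cut(.data$true_fdr, breaks = breaks,
                            include.lowest = TRUE)) |>
    dplyr::group_by(.data$method, .data$bin) |>
    dplyr::summarise(coverage = mean(.data$covered),
                     n_intervals = dplyr::n(), .groups = "drop") |>
    tidyr::complete(.data$method, .data$bin,
                    fill = list(n_intervals = 0L)) |>
    dplyr::mutate(bin_mid = mids[as.integer(.data$bin)], .after = "bin")
}
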