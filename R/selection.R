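#' Benjamini-Hochberg step-up selection of thresholds
#'
#' Sorts the per-threshold Wald p-values and finds
#' \eqn{R = \max\{i : P_{(i)} < i\alpha/|T|\}} (0 if no index qualifies).
#' Selected thresholds are those with \eqn{P_t \le P_{(R)}}; rows tied at
#' the critical p-value are included, which is the standard BH rejection
#' set.
#'
#' @param pvals Numeric vector of p-values, one per candidate threshold;
#'   `NA` entries (undefined rows) are never selected and do not count
#'   toward \eqn{|T|}.
#' @param alpha Nominal level in (0, 1); default 0.05.
#'
#' @return A list with `R` (number selected), `alpha_star`
#'   (\eqn{R\alpha/|T|}, the adjusted interval level), `n_tests`
#'   (\eqn{|T|}), and `selected` (logical, aligned with `pvals`).
#' @examples
#' bh_select(c(0.001, 0.002, 0.02, 0.3, 0.9), alpha = 0.05)$R  # 3
#' @export
bh_select <- function(pvals, alpha = 0.05) {
  if (length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  ok <- !is.na(pvals)
  nT <- sum(ok)
  if (nT == 0) {
    return(list(R = 0L, alpha_star = 0, n_tests = 0L,
                selected = rep(FALSE, length(pvals))))
  }
  ps <- sort(pvals[ok])
  pass <- which(ps < seq_len(nT) * alpha / nT)
  R <- if (length(pass)) max(pass) else 0L
  selected <- rep(FALSE, length(pvals))
  if (R > 0) selected[ok] <- pvals[ok] <= ps[R]
  list(R = as.integer(R), alpha_star = R * alpha / nT,
       n_tests = as.integer(nT), selected = selected)
}

#' FCR adjustment of the intervals at BH-selected thresholds
#'
#' Widens the confidence intervals of the selected thresholds to level
#' \eqn{\alpha^* = R\alpha/|T|}:
#' \eqn{\exp\{\log \widehat{FDR}_r \pm z_{\alpha^*/2} \sigma_{\log,r}\}}.
#' With `R < |T|` the adjusted intervals are strictly wider than the
#' nominal \eqn{1-\alpha} intervals; with `R = |T|` they coincide. The
#' widening compensates for having looked at the data to pick the
#' thresholds, so that the expected proportion of selected intervals
#' missing their true FDR (the false coverage-statement rate) stays at or
#' below \eqn{\alpha}.
#'
#' @param table An `fdr_table` (see [fdr_table()]).
#' @param alpha Nominal FCR level; default 0.05.
#'
#' @return The table with columns `selected_by` (logical),
#'   `adj_ci_lower`/`adj_ci_upper` (`NA` on non-selected rows), and
#'   attributes `R`, `alpha_star`, `alpha`.
#' @export
fcr_adjust <- function(table, alpha = 0.05) {
  sel <- bh_select(table$wald_p, alpha = alpha)
  table$selected_by <- sel$selected
  adj_lo <- rep(NA_real_, nrow(table))
  adj_hi <- rep(NA_real_, nrow(table))
  if (sel$R > 0) {
    z <- stats::qnorm(1 - sel$alpha_star / 2)
    i <- sel$selected
    adj_lo[i] <- exp(log(table$fdr[i]) - z * table$se_log[i])
    adj_hi[i] <- exp(log(table$fdr[i]) + z * table$se_log[i])
  }
  table$adj_ci_lower <- adj_lo
  table$adj_ci_upper <- adj_hi
  attr(table, "R") <- sel$R
  attr(table, "alpha_star") <- sel$alpha_star
  attr(table, "alpha") <- alpha
  table
}

#' Comparison selectors: interval upper bound below 1, or point estimate
#' below a cut
#'
#' `select_ucb()` flags every defined threshold whose unadjusted interval
#' has upper bound strictly below 1 — "some discoveries must be true".
#' `select_point()` flags defined thresholds whose FDR point estimate is
#' strictly below `cut` (default 0.2). Both are naive post-hoc rules used
#' as comparators for the FCR procedure; neither adjusts the intervals for
#' selection.
#'
#' @inheritParams fcr_adjust
#' @param cut Point-estimate cutoff for `select_point()`.
#'
#' @return Logical vector aligned with the table rows.
#' @export
select_ucb <- function(table) {
  table$defined & !is.na(table$ci_upper) & table$ci_upper < 1
}

#' @rdname select_ucb
#' @export
select_point <- function(table, cut = 0.2) {
  table$defined & !is.na(table$fdr) & table$fdr < cut
}

#' Apply all three selection rules to an FDR table
#'
#' Convenience wrapper: adds `selected_by` with FCR-adjusted bounds
#' ([fcr_adjust()]), `selected_ucb` ([select_ucb()]), and `selected_m2`
#' ([select_point()]).
#'
#' @inheritParams fcr_adjust
#' @param m2_cut Point-estimate cutoff for the M.2 rule.
#'
#' @return The table with the three selection columns and adjusted bounds.
#' @examples
#' set.seed(1)
#' p <- c(runif(1900), runif(100, 0, 1e-5))
#' perm <- matrix(runif(2000 * 20), 2000, 20)
#' tab <- fdr_table(p, perm) |> fdr_select()
#' dplyr::filter(tab, selected_by)
#' @export
fdr_select <- function(table, alpha = 0.05, m2_cut = 0.2) {
  table <- fcr_adjust(table, alpha = alpha)
  table$selected_ucb <- select_ucb(table)
  table$selected_m2 <- select_point(table, cut = m2_cut)
  table
}
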