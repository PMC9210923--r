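#' Estimate the null proportion from observed and permuted rejection counts
#'
#' \eqn{\hat\pi_0 = \frac{(m - S)/m}{(m - \bar V)/m}}, the fraction of
#' non-rejected tests relative to the fraction expected under the null,
#' truncated to \[0, 1\].
#'
#' @param m Number of tests.
#' @param S Observed rejection count at the threshold.
#' @param Vbar Mean permutation rejection count at the threshold
#'   (must be < m).
#'
#' @return Estimated proportion of true null hypotheses, in \[0, 1\].
#'   Vectorized over `S` and `Vbar`.
#' @examples
#' estimate_pi0(2000, 100, 10)  # 1900/1990
#' @export
estimate_pi0 <- function(m, S, Vbar) {
  if (any(Vbar >= m)) stop("Vbar must be smaller than m", call. = FALSE)
  pmin(pmax((m - S) / (m - Vbar), 0), 1)
}

#' Permutation-based pFDR point estimate
#'
#' \eqn{\widehat{FDR}_t = \hat\pi_0 \bar V_t / S_t}, the null-scaled ratio of
#' the expected null rejection count to the observed rejection count. The
#' estimate targets the positive FDR, \eqn{E[F/S \mid S > 0]}, and is
#' therefore undefined when `S = 0`. By default it is capped at 1, since
#' pFDR cannot exceed 1.
#'
#' @inheritParams estimate_pi0
#' @param pi0 Estimated null proportion (see [estimate_pi0()]).
#' @param cap_at_one Truncate the estimate at 1 (default `TRUE`).
#'
#' @return The FDR point estimate; `NA` where `S = 0`. Vectorized.
#' @examples
#' mv_fdr_point(2000, 100, 10, estimate_pi0(2000, 100, 10))
#' @export
mv_fdr_point <- function(m, S, Vbar, pi0, cap_at_one = TRUE) {
  out <- ifelse(S > 0, pi0 * Vbar / S, NA_real_)
  if (cap_at_one) out <- pmin(out, 1)
  out
}

#' Delta-method standard error of the log FDR estimate
#'
#' The variance of \eqn{\log \widehat{FDR}_t} decomposes into a
#' binomial-style term for the observed rejection count and a term for the
#' mean permutation count that shrinks with the number of permutations `P`
#' and is inflated by an over-dispersion factor `c1` reflecting dependence
#' among tests:
#' \deqn{\sigma^2 = \frac{m - S}{m S} + c_1 \frac{m - \bar V}{P m \bar V}.}
#' When `c1 = NULL` it is estimated per threshold as the ratio of the
#' sample variance of the permutation counts to the binomial variance
#' \eqn{m (\bar V/m)(1 - \bar V/m)}, floored at 1 (never less dispersed than
#' binomial). Degenerate `S = m` or `Vbar = m` cases clamp the
#' corresponding term at 0.
#'
#' @inheritParams estimate_pi0
#' @param var_counts Sample variance of the per-permutation rejection
#'   counts at the threshold (`NA` allowed; forces `c1 = 1`).
#' @param n_perm Number of permutation replicates P.
#' @param c1 Over-dispersion factor; `NULL` (default) estimates it from
#'   `var_counts`.
#'
#' @return The standard error of `log(fdr_hat)`; vectorized.
#' @examples
#' se_log_fdr(2000, 100, 10, var_counts = NA, n_perm = 20, c1 = 1)
#' @export
se_log_fdr <- function(m, S, Vbar, var_counts, n_perm, c1 = NULL) {
  if (any(S <= 0) || any(Vbar <= 0)) {
    stop("se_log_fdr requires S > 0 and Vbar > 0", call. = FALSE)
  }
  c1v <- resolve_c1(c1, var_counts, Vbar, m, length(S))
  term_obs <- pmax((m - S) / (m * S), 0)
  term_perm <- pmax(c1v * (m - Vbar) / (n_perm * m * Vbar), 0)
  sqrt(term_obs + term_perm)
}

resolve_c1 <- function(c1, var_counts, Vbar, m, n_out) {
  if (!is.null(c1)) {
    if (any(c1 <= 0)) stop("c1 must be positive", call. = FALSE)
    return(rep_len(c1, n_out))
  }
  binom_var <- Vbar * (1 - Vbar / m)
  c1v <- var_counts / binom_var
  c1v[!is.finite(c1v) | c1v < 1] <- 1
  c1v
}

#' Log-normal confidence interval for the FDR estimate
#'
#' \eqn{\exp\{\log \widehat{FDR} \pm z_{(1-cl)/2}\, \sigma_{\log}\}}. The
#' interval is multiplicative-symmetric about the point estimate; its upper
#' bound may exceed 1, which is deliberate — selection rules compare the
#' upper bound to 1.
#'
#' @param fdr_hat FDR point estimate(s), > 0.
#' @param se_log Standard error(s) of the log estimate, > 0.
#' @param cl Confidence level in (0, 1); default 0.95.
#'
#' @return A tibble with columns `ci_lower` and `ci_upper`.
#' @examples
#' fdr_confint(0.0955, 0.12031)
#' @export
fdr_confint <- function(fdr_hat, se_log, cl = 0.95) {
  if (length(cl) != 1 || is.na(cl) || cl <= 0 || cl >= 1) {
    stop("cl must lie in (0, 1)", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - cl) / 2)
  tibble::tibble(
    ci_lower = exp(log(fdr_hat) - z * se_log),
    ci_upper = exp(log(fdr_hat) + z * se_log)
  )
}

#' One-sided Wald p-value for evidence that FDR < 1
#'
#' Tests \eqn{H_0: \log FDR_t = 0} against \eqn{H_a: \log FDR_t < 0} with
#' \eqn{Z_t = \log(\widehat{FDR}_t)/\sigma_{\log}} and
#' \eqn{P_t = \Phi(Z_t)}. A capped estimate of 1 gives \eqn{Z_t = 0} and
#' \eqn{P_t = 0.5}: no evidence of any true discoveries.
#'
#' @inheritParams fdr_confint
#'
#' @return P-value(s) in (0, 1\]; small values mean strong evidence that
#'   some discoveries at the threshold are true.
#' @examples
#' wald_pvalue(1, 0.3)                        # 0.5
#' wald_pvalue(exp(-1.6448536 * 0.2), 0.2)    # 0.05
#' @export
wald_pvalue <- function(fdr_hat, se_log) {
  if (any(se_log <= 0, na.rm = TRUE)) {
    stop("se_log must be positive", call. = FALSE)
  }
  pmax(stats::pnorm(log(fdr_hat) / se_log), 1e-300)
}

# Vectorized estimation kernel over a threshold grid, from sufficient
# statistics. S: integer vector (one per threshold); perm_counts: P x |T|
# matrix. Returns a list of aligned columns.
mv_fdr_kernel <- function(S, perm_counts, m, cl = 0.95, c1 = NULL,
                          cap_at_one = TRUE) {
  n_perm <- nrow(perm_counts)
  nt <- length(S)
  Vbar_raw <- colMeans(perm_counts)
  var_counts <- if (n_perm >= 2) {
    colSums((perm_counts - rep(Vbar_raw, each = n_perm))^2) / (n_perm - 1)
  } else {
    rep(NA_real_, nt)
  }
  defined <- S > 0
  # continuity: Vbar = 0 with S > 0 would give log(0); substitute half a
  # count spread over the permutations, conservatively small
  vbar_adjusted <- defined & Vbar_raw == 0
  Vbar <- ifelse(vbar_adjusted, 0.5 / n_perm, Vbar_raw)

  c1v <- resolve_c1(c1, var_counts, Vbar, m, nt)
  pi0 <- estimate_pi0(m, S, pmin(Vbar, m - 1e-12))
  fdr <- mv_fdr_point(m, S, Vbar, pi0, cap_at_one = cap_at_one)

  term_obs <- pmax((m - S) / (m * S), 0)
  term_perm <- pmax(c1v * (m - Vbar) / (n_perm * m * Vbar), 0)
  se <- ifelse(defined, sqrt(term_obs + term_perm), NA_real_)

  z <- stats::qnorm(1 - (1 - cl) / 2)
  ci_lower <- exp(log(fdr) - z * se)
  ci_upper <- exp(log(fdr) + z * se)
  wald_p <- ifelse(defined, pmax(stats::pnorm(log(fdr) / se), 1e-300),
                   NA_real_)

  list(S = as.integer(S), Vbar = Vbar, var_perm_counts = var_counts,
       c1 = c1v, pi0 = ifelse(defined, pi0, NA_real_), fdr = fdr,
       se_log = se, ci_lower = ci_lower, ci_upper = ci_upper,
       wald_p = wald_p, defined = defined, vbar_adjusted = vbar_adjusted)
}

new_fdr_table <- function(thresholds, kern, m, n_perm, cl) {
  out <- tibble::tibble(
    threshold = thresholds,
    neg_log10_t = -log10(thresholds),
    S = kern$S,
    Vbar = kern$Vbar,
    var_perm_counts = kern$var_perm_counts,
    c1 = kern$c1,
    pi0 = kern$pi0,
    fdr = kern$fdr,
    se_log = kern$se_log,
    ci_lower = kern$ci_lower,
    ci_upper = kern$ci_upper,
    wald_p = kern$wald_p,
    defined = kern$defined,
    vbar_adjusted = kern$vbar_adjusted
  )
  attr(out, "m") <- m
  attr(out, "n_perm") <- n_perm
  attr(out, "cl") <- cl
  class(out) <- c("fdr_table", class(out))
  out
}

#' FDR estimates with confidence intervals over a threshold grid
#'
#' The workhorse of the package: for every threshold in a nested grid it
#' computes the observed rejection count `S`, the mean and variance of the
#' permutation rejection counts, the null-proportion estimate, the pFDR
#' point estimate, the delta-method standard error of its log, a log-normal
#' confidence interval, and a one-sided Wald p-value for FDR < 1. Rows with
#' `S = 0` are flagged `defined = FALSE` (no pFDR exists); rows where every
#' permutation produced zero rejections use the continuity substitution
#' `Vbar = 0.5/P` and are flagged `vbar_adjusted`.
#'
#' @param pvals Numeric vector of observed p-values in (0, 1\].
#' @param perms Permutation replicates: a matrix with one column of null
#'   p-values per permutation, or a [permutation_ensemble()] (which may
#'   carry per-threshold counts instead of p-values).
#' @param thresholds Threshold grid from [threshold_grid()], ordered or
#'   orderable loose to strict.
#' @param cl Confidence level for the (unadjusted) intervals.
#' @param c1 Over-dispersion factor for the permutation-count variance;
#'   `NULL` (default) estimates it from the permutation counts per
#'   threshold, floored at 1.
#' @param rule Rejection rule at the threshold boundary (see
#'   [count_rejections()]).
#' @param cap_at_one Cap the point estimate at 1 (default `TRUE`).
#'
#' @return A tibble of class `fdr_table`, one row per threshold ordered
#'   loose to strict, with attributes `m`, `n_perm`, `cl`.
#' @examples
#' set.seed(7)
#' p <- c(runif(180), runif(20, 0, 1e-4))
#' perm <- matrix(runif(200 * 10), 200, 10)
#' fdr_table(p, perm, threshold_grid(1, 3, 0.5))
#' @export
fdr_table <- function(pvals, perms, thresholds = threshold_grid(),
                      cl = 0.95, c1 = NULL,
                      rule = c("strict", "nonstrict"), cap_at_one = TRUE) {
  rule <- match.arg(rule)
  check_pvalues(pvals, "observed p-values")
  thresholds <- check_thresholds(thresholds)
  if (length(cl) != 1 || cl <= 0 || cl >= 1) {
    stop("cl must lie in (0, 1)", call. = FALSE)
  }
  if (!inherits(perms, "perm_ensemble")) {
    perms <- permutation_ensemble(perms, rule = rule)
  }
  if (perms$m != length(pvals)) {
    stop("observed p-values and permutation ensemble disagree on m (",
         length(pvals), " vs ", perms$m, ")", call. = FALSE)
  }
  S <- count_kernel(pvals, thresholds, rule)
  perm_counts <- ensemble_counts(perms, thresholds, rule)
  fdr_table_counts(S, perm_counts, m = perms$m, thresholds = thresholds,
                   cl = cl, c1 = c1, cap_at_one = cap_at_one)
}

#' @rdname fdr_table
#' @param obs_counts Observed rejection counts, one per threshold.
#' @param perm_counts Matrix of permutation rejection counts, one row per
#'   permutation and one column per threshold.
#' @param m Total number of tests.
#' @details `fdr_table_counts()` is the sufficient-statistic entry point:
#'   rejection counts at the grid thresholds carry all the information the
#'   estimator uses, so pre-reduced counts (e.g. from a filtered
#'   large-scale analysis) give bit-identical results to raw p-values.
#' @export
fdr_table_counts <- function(obs_counts, perm_counts, m,
                             thresholds = threshold_grid(), cl = 0.95,
                             c1 = NULL, cap_at_one = TRUE) {
  m <- as.integer(m)
  ord <- order(thresholds, decreasing = TRUE)
  thresholds <- check_thresholds(thresholds)
  perm_counts <- as.matrix(perm_counts)
  if (length(obs_counts) != length(thresholds) ||
      ncol(perm_counts) != length(thresholds)) {
    stop("counts must align with the threshold grid", call. = FALSE)
  }
  obs_counts <- obs_counts[ord]
  perm_counts <- perm_counts[, ord, drop = FALSE]
  if (any(obs_counts < 0) || any(obs_counts > m) ||
      any(perm_counts < 0) || any(perm_counts > m)) {
    stop("rejection counts must lie in [0, m]", call. = FALSE)
  }
  if (is.unsorted(rev(obs_counts))) {
    stop("observed counts must be non-increasing across the nested grid",
         call. = FALSE)
  }
  kern <- mv_fdr_kernel(obs_counts, perm_counts, m = m, cl = cl, c1 = c1,
                        cap_at_one = cap_at_one)
  new_fdr_table(thresholds, kern, m = m, n_perm = nrow(perm_counts), cl = cl)
}
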