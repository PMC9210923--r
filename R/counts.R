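#' Count rejections at a discovery threshold
#'
#' The number of tests whose p-value falls below the cutoff. The default
#' rule is strict (`p < t`): a p-value exactly at the boundary is not a
#' rejection, so observed and permuted results are treated symmetrically.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param threshold P-value cutoff(s) in (0, 1); vectorized.
#' @param rule `"strict"` counts `p < t` (default); `"nonstrict"` counts
#'   `p <= t`.
#'
#' @return Integer vector of rejection counts, one per threshold.
#' @examples
#' count_rejections(c(0.001, 0.01, 0.5), 0.01)  # boundary excluded -> 1
#' @export
count_rejections <- function(p, threshold, rule = c("strict", "nonstrict")) {
  rule <- match.arg(rule)
  check_pvalues(p)
  if (length(threshold) == 0 || any(threshold <= 0) || any(threshold >= 1)) {
    stop("threshold must lie in (0, 1)", call. = FALSE)
  }
  count_kernel(p, threshold, rule)
}

# Hot path used by the simulation engine: no validation. Pre-filters to the
# loosest cutoff so the per-threshold scan touches only candidate p-values.
count_kernel <- function(p, thresholds, rule = "strict") {
  tmax <- max(thresholds)
  pp <- if (rule == "strict") p[p < tmax] else p[p <= tmax]
  if (rule == "strict") {
    vapply(thresholds, function(t) sum(pp < t), integer(1))
  } else {
    vapply(thresholds, function(t) sum(pp <= t), integer(1))
  }
}

#' Bundle permutation replicates of null p-values (or their rejection counts)
#'
#' Permutation replicates can be carried either as full p-value vectors (one
#' per replicate) or, equivalently, as per-threshold rejection counts. The
#' counts form is a lossless sufficient representation: every estimate in
#' [fdr_table()] depends on the permutations only through the number of
#' tests `m` and the rejection counts at the grid thresholds.
#'
#' @param pvalues A numeric matrix of null p-values with one column per
#'   permutation replicate (`m` rows, `P` columns), or `NULL` when counts
#'   are supplied.
#' @param counts An integer matrix of rejection counts with one row per
#'   permutation and one column per threshold, or `NULL`.
#' @param m Number of tests; required (and checked) for the counts form,
#'   inferred from `pvalues` otherwise.
#' @param thresholds Threshold grid the counts refer to (counts form only),
#'   ordered loose to strict.
#' @param rule Rejection rule used when reducing p-values to counts.
#'
#' @return An object of class `perm_ensemble` with elements `m`, `n_perm`,
#'   and either `pvalues` or `counts` + `thresholds`.
#' @examples
#' pe <- permutation_ensemble(matrix(runif(100), ncol = 5))
#' pe$n_perm
#' @export
permutation_ensemble <- function(pvalues = NULL, counts = NULL, m = NULL,
                                 thresholds = NULL,
                                 rule = c("strict", "nonstrict")) {
  rule <- match.arg(rule)
  if (is.null(pvalues) == is.null(counts)) {
    stop("supply exactly one of `pvalues` or `counts`", call. = FALSE)
  }
  if (!is.null(pvalues)) {
    pvalues <- as.matrix(pvalues)
    check_pvalues(as.vector(pvalues), "permutation p-values")
    out <- list(m = nrow(pvalues), n_perm = ncol(pvalues),
                pvalues = pvalues, rule = rule)
  } else {
    counts <- as.matrix(counts)
    thresholds <- check_thresholds(thresholds)
    if (ncol(counts) != length(thresholds)) {
      stop("`counts` needs one column per threshold", call. = FALSE)
    }
    if (is.null(m)) stop("`m` is required with the counts form", call. = FALSE)
    if (any(counts < 0) || any(counts > m)) {
      stop("counts must lie in [0, m]", call. = FALSE)
    }
    out <- list(m = as.integer(m), n_perm = nrow(counts),
                counts = counts, thresholds = thresholds, rule = rule)
  }
  if (out$n_perm < 1) stop("need at least one permutation", call. = FALSE)
  structure(out, class = "perm_ensemble")
}

# Reduce an ensemble to a P x |T| count matrix for the given grid.
ensemble_counts <- function(ens, thresholds, rule = "strict") {
  if (!is.null(ens$counts)) {
    idx <- match(round(-log10(thresholds), 10),
                 round(-log10(ens$thresholds), 10))
    if (anyNA(idx)) {
      stop("counts ensemble does not cover the requested thresholds",
           call. = FALSE)
    }
    return(ens$counts[, idx, drop = FALSE])
  }
  t(apply(ens$pvalues, 2, count_kernel, thresholds = thresholds, rule = rule))
}

#' Summarize permutation rejection counts at a threshold
#'
#' @param ens A [permutation_ensemble()], or a numeric matrix of null
#'   p-values with one column per permutation.
#' @param threshold A single p-value cutoff in (0, 1).
#' @inheritParams count_rejections
#'
#' @return A one-row tibble with `Vbar` (mean rejection count across
#'   permutations), `var_counts` (unbiased sample variance, `NA` when only
#'   one permutation is available), and `n_perm`.
#' @examples
#' pe <- permutation_ensemble(counts = matrix(c(3L, 5L), nrow = 2),
#'                            m = 10, thresholds = 0.05)
#' summarize_permutations(pe, 0.05)  # Vbar 4, var 2
#' @export
summarize_permutations <- function(ens, threshold,
                                   rule = c("strict", "nonstrict")) {
  rule <- match.arg(rule)
  if (!inherits(ens, "perm_ensemble")) ens <- permutation_ensemble(ens, rule = rule)
  stopifnot(length(threshold) == 1, threshold > 0, threshold < 1)
  cts <- as.vector(ensemble_counts(ens, threshold, rule))
  tibble::tibble(
    Vbar = mean(cts),
    var_counts = if (length(cts) >= 2) stats::var(cts) else NA_real_,
    n_perm = length(cts)
  )
}
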