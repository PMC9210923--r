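#' Build a nested grid of candidate discovery thresholds
#'
#' Candidate p-value cutoffs are specified on the \eqn{-\log_{10}} scale and
#' returned as p-value thresholds ordered from loose to strict, so that the
#' rejection region at each threshold is nested inside the previous one.
#'
#' @param neg_log10_min,neg_log10_max Range of the grid on the
#'   \eqn{-\log_{10}(p)} scale. Defaults cover \eqn{10^{-2}} down to
#'   \eqn{10^{-6}}.
#' @param step Grid spacing on the \eqn{-\log_{10}} scale.
#'
#' @return A numeric vector of p-value thresholds, strictly decreasing
#'   (increasing stringency), all in (0, 1).
#' @examples
#' threshold_grid()           # 41 thresholds, 1e-2 ... 1e-6
#' threshold_grid(2, 3, 0.5)  # 0.01, 0.00316..., 0.001
#' @export
threshold_grid <- function(neg_log10_min = 2, neg_log10_max = 6, step = 0.1) {
  stopifnot(step > 0, neg_log10_max >= neg_log10_min, neg_log10_min > 0)
  10^(-seq(neg_log10_min, neg_log10_max, by = step))
}

# Validate a threshold vector: in (0,1), strictly monotone. Returns the
# thresholds sorted strictly decreasing (loose -> strict).
check_thresholds <- function(thresholds) {
  if (length(thresholds) == 0) {
    stop("threshold grid is empty", call. = FALSE)
  }
  if (!is.numeric(thresholds) || anyNA(thresholds) ||
      any(thresholds <= 0) || any(thresholds >= 1)) {
    stop("thresholds must be numeric and in (0, 1)", call. = FALSE)
  }
  d <- diff(thresholds)
  if (any(d == 0) || (any(d > 0) && any(d < 0))) {
    stop("thresholds must be strictly monotone", call. = FALSE)
  }
  sort(thresholds, decreasing = TRUE)
}

check_pvalues <- function(p, what = "p-values") {
  if (length(p) == 0) stop(what, ": empty p-value vector", call. = FALSE)
  if (!is.numeric(p) || anyNA(p) || any(!is.finite(p)) ||
      any(p <= 0) || any(p > 1)) {
    bad <- which(!is.finite(p) | p <= 0 | p > 1)
    stop(what, ": values outside (0, 1] at positions ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  invisible(p)
}
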