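#' Specify a block-correlated simulation scenario
#'
#' The validation design: `n_blocks` independent blocks of `block_size`
#' equicorrelated Gaussian predictors (within-block correlation `rho`,
#' marginal SD `sigma`), one Gaussian outcome per block generated as
#' `Y_l = X_l beta_l + eps` with noise SD `sigma`. Every predictor is
#' tested against every outcome, so `m = n_predictors * n_blocks` marginal
#' tests. The named scenarios vary how many blocks carry signal and how
#' strong it is:
#' * A — 5 non-null blocks, all five within-block coefficients 0.05
#' * B — 10 non-null blocks at 0.05
#' * C — 5 non-null blocks at 0.075
#' * D — 10 non-null blocks at 0.075
#' * E — global null (all coefficients 0)
#'
#' Within a non-null block, every one of its `block_size` predictors is
#' marginally associated with the block outcome (directly or through the
#' within-block correlation), so the truly null predictor-outcome pairs
#' are exactly the cross-block pairs plus all pairs of null blocks.
#'
#' @param scenario One of `"A"`..`"E"`, or `"custom"` with
#'   `n_nonnull_blocks`/`effect` supplied.
#' @param n Sample size per replicate.
#' @param n_blocks,block_size Number of predictor blocks and predictors
#'   per block.
#' @param rho Within-block correlation of predictors.
#' @param sigma Marginal SD of predictors and of outcome noise.
#' @param n_perm Permutation replicates per analysis.
#' @param thresholds Candidate discovery-threshold grid.
#' @param alpha Nominal FCR level for the BH selection.
#' @param cl Confidence level of the unadjusted intervals.
#' @param m2_cut Point-estimate cutoff of the M.2 comparator.
#' @param n_nonnull_blocks,effect Override the per-scenario signal layout
#'   (`scenario = "custom"`).
#'
#' @return An object of class `scenario_spec`: a list with the design
#'   constants, the `n_predictors x n_blocks` coefficient matrix `beta`,
#'   and `null_pairs`, the logical vector (outcome-major order, length
#'   `m`) marking the truly null predictor-outcome pairs.
#' @examples
#' sp <- scenario_spec("A")
#' sp$m; sum(!sp$null_pairs)  # 2000 tests, 25 false nulls
#' @export
scenario_spec <- function(scenario = c("A", "B", "C", "D", "E", "custom"),
                          n = 200, n_blocks = 20, block_size = 5,
                          rho = 0.3, sigma = 1, n_perm = 20,
                          thresholds = threshold_grid(),
                          alpha = 0.05, cl = 0.95, m2_cut = 0.2,
                          n_nonnull_blocks = NULL, effect = NULL) {
  scenario <- match.arg(scenario)
  layouts <- list(A = c(5, 0.05), B = c(10, 0.05),
                  C = c(5, 0.075), D = c(10, 0.075), E = c(0, 0))
  if (scenario == "custom") {
    stopifnot(!is.null(n_nonnull_blocks), !is.null(effect))
  } else {
    n_nonnull_blocks <- layouts[[scenario]][1]
    effect <- layouts[[scenario]][2]
  }
  stopifnot(n_nonnull_blocks <= n_blocks,
            rho > -1 / (block_size - 1), rho < 1, sigma > 0)
  n_predictors <- n_blocks * block_size
  m <- n_predictors * n_blocks
  block_of <- rep(seq_len(n_blocks), each = block_size)

  beta <- matrix(0, n_predictors, n_blocks)
  for (l in seq_len(n_nonnull_blocks)) beta[block_of == l, l] <- effect

  # outcome-major order: pair (predictor i, outcome j) at (j-1)*n_pred + i
  nonnull <- matrix(FALSE, n_predictors, n_blocks)
  for (l in seq_len(n_nonnull_blocks)) nonnull[block_of == l, l] <- TRUE

  structure(list(
    scenario = scenario, n = n, n_blocks = n_blocks,
    block_size = block_size, n_predictors = n_predictors, m = m,
    rho = rho, sigma = sigma, n_perm = n_perm,
    thresholds = check_thresholds(thresholds),
    alpha = alpha, cl = cl, m2_cut = m2_cut,
    n_nonnull_blocks = n_nonnull_blocks, effect = effect,
    beta = beta, block_of = block_of,
    null_pairs = as.vector(!nonnull)
  ), class = "scenario_spec")
}

#' Simulate one replicate dataset from a scenario
#'
#' Predictors are drawn block-wise from a multivariate normal with
#' compound-symmetric covariance \eqn{\Sigma_l = \sigma^2[(1-\rho)I +
#' \rho J]}, generated exactly via the one-factor representation
#' \eqn{X = \sigma(\sqrt{\rho}\, u\, 1' + \sqrt{1-\rho}\, Z)} with a
#' shared standard-normal factor per block; blocks are mutually
#' independent. Each block's outcome is `Y_l = X_l beta_l + eps`,
#' `eps ~ N(0, sigma^2)` i.i.d.
#'
#' @param spec A [scenario_spec()].
#'
#' @return A list with `X` (`n x n_predictors`) and `Y` (`n x n_blocks`).
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  n <- spec$n
  if (spec$rho <= -1 / (spec$block_size - 1)) {
    stop("rho makes the block covariance non-positive-definite",
         call. = FALSE)
  }
  Z <- matrix(stats::rnorm(n * spec$n_predictors), n, spec$n_predictors)
  U <- matrix(stats::rnorm(n * spec$n_blocks), n, spec$n_blocks)
  X <- spec$sigma * (sqrt(1 - spec$rho) * Z +
                       sqrt(spec$rho) * U[, spec$block_of, drop = FALSE])
  Y <- X %*% spec$beta +
    spec$sigma * matrix(stats::rnorm(n * spec$n_blocks), n, spec$n_blocks)
  list(X = X, Y = Y)
}

# Centered-matrix correlation p-values; returns n_pred x n_out matrix.
pv_kernel <- function(Xc, Yc, xs, n) {
  ys <- sqrt(colSums(Yc^2))
  r <- crossprod(Xc, Yc) / outer(xs, ys)
  r <- pmin(pmax(r, -1), 1)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(-abs(tt), df = n - 2)
}

#' Marginal association p-values for every predictor-outcome pair
#'
#' Two-sided p-value of the simple-linear-regression slope (identically,
#' the Pearson-correlation t-test on `n - 2` degrees of freedom) for each
#' predictor-outcome pair.
#'
#' @param X Numeric predictor matrix (`n x n_predictors`).
#' @param Y Numeric outcome matrix (`n x n_outcomes`).
#'
#' @return Numeric vector of `n_predictors * n_outcomes` p-values in
#'   outcome-major order: all predictors against outcome 1, then all
#'   against outcome 2, and so on.
#' @export
marginal_pvalues <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y need equal row counts", call. = FALSE)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  xs <- sqrt(colSums(Xc^2))
  if (any(xs == 0) || any(colSums(Yc^2) == 0)) {
    stop("constant column: p-values undefined", call. = FALSE)
  }
  as.vector(pv_kernel(Xc, Yc, xs, n))
}

#' Permute outcomes jointly with respect to predictors
#'
#' Applies one shared row permutation to the whole outcome matrix. The
#' predictor rows are untouched, so dependencies within the predictor set
#' and within the outcome set are both preserved while every
#' predictor-outcome association is broken — the permutation null for the
#' marginal tests.
#'
#' @param Y Outcome matrix.
#' @param perm Integer row permutation; drawn uniformly at random when
#'   omitted.
#'
#' @return The row-permuted outcome matrix.
#' @examples
#' Y <- matrix(1:6, 3, 2)
#' permute_outcomes(Y, perm = c(2, 3, 1))
#' @export
permute_outcomes <- function(Y, perm = sample.int(nrow(Y))) {
  Y <- as.matrix(Y)
  stopifnot(length(perm) == nrow(Y), !anyDuplicated(perm),
            all(perm >= 1), all(perm <= nrow(Y)))
  Y[perm, , drop = FALSE]
}
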