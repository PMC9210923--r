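# Independent brute-force oracles used to check the vectorized paths.

# element-by-element rejection count
naive_count <- function(p, t, strict = TRUE) {
  ct <- 0L
  for (x in p) {
    hit <- if (strict) x < t else x <= t
    if (hit) ct <- ct + 1L
  }
  ct
}

# step-up rule by exhaustive scan of all cutoffs, largest index first
bh_brute <- function(p, alpha) {
  n <- length(p)
  sp <- sort(p)
  for (i in rev(seq_len(n))) {
    if (sp[i] < i * alpha / n) return(i)
  }
  0L
}

# hand-rolled single-threshold MV estimate from counts (scalar arithmetic,
# no shared code with the package kernel)
hand_estimate <- function(m, S, perm_counts, cl = 0.95, c1 = NULL) {
  P <- length(perm_counts)
  Vbar <- sum(perm_counts) / P
  vc <- sum((perm_counts - Vbar)^2) / (P - 1)
  if (S > 0 && Vbar == 0) Vbar <- 0.5 / P
  if (is.null(c1)) {
    c1 <- vc / (Vbar * (1 - Vbar / m))
    if (!is.finite(c1) || c1 < 1) c1 <- 1
  }
  pi0 <- min(max((m - S) / (m - Vbar), 0), 1)
  fdr <- min(pi0 * Vbar / S, 1)
  s2 <- max((m - S) / (m * S), 0) + max(c1 * (m - Vbar) / (P * m * Vbar), 0)
  se <- sqrt(s2)
  z <- qnorm(1 - (1 - cl) / 2)
  list(Vbar = Vbar, pi0 = pi0, fdr = fdr, se = se,
       lo = exp(log(fdr) - z * se), hi = exp(log(fdr) + z * se),
       wald = pnorm(log(fdr) / se))
}

# small observed + permutation p-value fixture with planted signal
toy_fixture <- function(seed = 42, m = 500, n_perm = 8, n_signal = 25) {
  set.seed(seed)
  list(
    pvals = c(runif(m - n_signal), runif(n_signal, 0, 1e-4)),
    perms = matrix(runif(m * n_perm), m, n_perm),
    m = m, n_perm = n_perm
  )
}
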