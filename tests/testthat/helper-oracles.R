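# Independent oracles used across test files. Each reimplements the checked
# quantity from its definition, never through the package's code path.

# Exhaustive-permutation Mann-Whitney: U by pair counting, two-sided p by
# enumerating every assignment of the pooled values to the two groups.
perm_mw_oracle <- function(x, y) {
  U <- 0
  for (xi in x) U <- U + sum(xi > y) + 0.5 * sum(xi == y)
  pool <- c(x, y)
  n <- length(pool)
  combos <- utils::combn(n, length(x))
  mid <- length(x) * length(y) / 2
  Us <- apply(combos, 2, function(ix) {
    xx <- pool[ix]; yy <- pool[-ix]
    u <- 0
    for (xi in xx) u <- u + sum(xi > yy) + 0.5 * sum(xi == yy)
    u
  })
  list(U = U, p = mean(abs(Us - mid) >= abs(U - mid) - 1e-12))
}

# AUC by brute-force enumeration of all case-control pairs.
pair_auc_oracle <- function(cases, controls) {
  wins <- 0
  for (s in cases) wins <- wins + sum(s > controls) + 0.5 * sum(s == controls)
  wins / (length(cases) * length(controls))
}

# Per-fold logistic refit through stats::glm.fit (independent IRLS).
loocv_glm_oracle <- function(X, y) {
  vapply(seq_len(nrow(X)), function(i) {
    g <- stats::glm.fit(cbind(1, X[-i, , drop = FALSE]), y[-i],
                        family = stats::binomial(),
                        control = stats::glm.control(epsilon = 1e-14,
                                                     maxit = 200))
    stats::plogis(sum(c(1, X[i, ]) * g$coefficients))
  }, numeric(1))
}

# Direct evaluation of the matched conditional log-likelihood, vectorized
# over a beta grid (single covariate).
cond_ll_direct <- function(beta_grid, x_by_stratum, case_pos) {
  vapply(beta_grid, function(b) {
    ll <- 0
    for (s in seq_along(x_by_stratum)) {
      e <- exp(x_by_stratum[[s]] * b)
      ll <- ll + x_by_stratum[[s]][case_pos[s]] * b - log(sum(e))
    }
    ll
  }, numeric(1))
}

# Matched strata with a known coefficient: member covariates are standard
# normal and the case within each stratum is drawn with probability
# proportional to exp(x * beta) (the conditional-logistic sampling scheme).
simulate_strata <- function(n_strata, m = 3, beta = 1, seed = 1) {
  set.seed(seed)
  size <- m + 1
  x <- rnorm(n_strata * size)
  stratum <- rep(seq_len(n_strata), each = size)
  case <- logical(n_strata * size)
  for (s in seq_len(n_strata)) {
    ix <- which(stratum == s)
    w <- exp(x[ix] * beta)
    case[sample(ix, 1, prob = w / sum(w))] <- TRUE
  }
  data.frame(stratum_id = stratum, group = ifelse(case, "case", "control"),
             x = x)
}
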