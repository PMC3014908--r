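# Unconditional logistic regression by Newton/IRLS, plus leave-one-out
# cross-validated probabilities and the cross-validated information
# criterion that scores candidate subsets in the exhaustive search.

logistic_loglik <- function(beta, X, y) {
  eta <- drop(X %*% beta)
  sum(stats::plogis(ifelse(y == 1, eta, -eta), log.p = TRUE))
}

#' Fit a logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit with an intercept added to the supplied
#' design. Newton steps with monotone step-halving; convergence when the
#' largest coefficient change is below `tol`. Quasi-separation and other
#' failures are reported through the `converged` flag rather than an error.
#'
#' @param X Numeric matrix of covariates (subjects x variables), without
#'   intercept column.
#' @param y 0/1 case indicator (both classes present).
#' @param tol Convergence tolerance on the max coefficient change
#'   (default 1e-8).
#' @param maxit Maximum Newton iterations (default 100).
#' @param start Optional warm-start coefficients (intercept first).
#' @return List with `beta` (intercept first), `loglik`, `converged`,
#'   `iterations`.
#' @export
fit_logistic <- function(X, y, tol = 1e-8, maxit = 100L, start = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) stop("'y' must contain both classes")
  Xd <- cbind(`(Intercept)` = 1, X)
  if (qr(Xd)$rank < ncol(Xd)) stop("design is rank deficient")
  p <- ncol(Xd)
  beta <- if (is.null(start)) c(stats::qlogis(mean(y)), numeric(p - 1L))
          else as.numeric(start)
  ll <- logistic_loglik(beta, Xd, y)
  converged <- FALSE
  it <- 0L
  while (it < maxit) {
    it <- it + 1L
    eta <- drop(Xd %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    g <- crossprod(Xd, y - mu)
    H <- crossprod(Xd * w, Xd)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    # monotone step-halving
    lam <- 1
    repeat {
      cand <- beta + lam * step
      ll_new <- logistic_loglik(cand, Xd, y)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-10) break
    }
    if (lam < 1e-10) break
    moved <- max(abs(lam * step))
    beta <- drop(cand)
    ll <- ll_new
    if (moved < tol) { converged <- TRUE; break }
  }
  names(beta) <- colnames(Xd)
  list(beta = beta, loglik = ll, converged = converged, iterations = it)
}

#' Leave-one-out cross-validated case probabilities
#'
#' For each subject the model is refitted on the remaining n - 1 subjects
#' (warm-started at the full-data solution) and the fitted logistic function
#' is evaluated at the held-out subject: exactly n fits, deterministic. If
#' any fold fails to converge the whole vector is flagged.
#'
#' @param X Covariate matrix (no intercept column).
#' @param y 0/1 case indicator.
#' @return Numeric vector of out-of-fold probabilities with attribute
#'   `converged` (FALSE if any fold failed).
#' @export
loocv_probs <- function(X, y) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (n < ncol(X) + 2L) stop("too few subjects for the subset size")
  full <- fit_logistic(X, y)
  start <- if (full$converged) full$beta else NULL
  probs <- numeric(n)
  ok <- TRUE
  for (i in seq_len(n)) {
    fit <- tryCatch(
      fit_logistic(X[-i, , drop = FALSE], y[-i], start = start),
      error = function(e) list(converged = FALSE))
    if (!isTRUE(fit$converged)) { ok <- FALSE; probs[i] <- NA_real_; next }
    probs[i] <- stats::plogis(sum(c(1, X[i, ]) * fit$beta))
  }
  attr(probs, "converged") <- ok
  probs
}

#' Cross-validated information criterion for a candidate subset
#'
#' Computes `-2 * sum(y*log(p) + (1-y)*log(1-p)) + 2 * (subset_size + 1)`
#' from out-of-fold probabilities, i.e. the Akaike-style criterion with the
#' Bernoulli log-likelihood replaced by its leave-one-out cross-validated
#' counterpart. Probabilities are clipped to `[1e-12, 1 - 1e-12]` before the
#' logs. With `penalty = FALSE` the `2(k+1)` term is dropped, leaving the
#' pure cross-validated deviance.
#'
#' @param cv_probs Out-of-fold case probabilities.
#' @param y 0/1 case indicator, same length.
#' @param subset_size Number of covariates in the candidate (intercept adds
#'   one parameter).
#' @param penalty Keep the `2(k+1)` parameter penalty (default TRUE).
#' @return The criterion value (`Inf` if any probability is missing).
#' @export
cv_aic <- function(cv_probs, y, subset_size, penalty = TRUE) {
  if (length(cv_probs) != length(y)) stop("length mismatch")
  if (anyNA(cv_probs)) return(Inf)
  p <- pmin(pmax(cv_probs, 1e-12), 1 - 1e-12)
  ll <- sum(y * log(p) + (1 - y) * log(1 - p))
  -2 * ll + if (penalty) 2 * (subset_size + 1) else 0
}
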