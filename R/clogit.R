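# Conditional logistic regression over 1:m matched strata, fitted by
# Newton-Raphson on the conditional likelihood, and the discriminant score
# (the linear predictor, i.e. the logit of the conditional-logistic
# function value) applied to arbitrary cohorts.

#' Conditional log-likelihood of matched strata
#'
#' Sum over strata of `x_case' beta - log(sum_j exp(x_j' beta))` where j
#' runs over the stratum members; the log-sum-exp is computed stably by
#' max-subtraction. Stratum-constant shifts of any covariate leave the value
#' unchanged (the conditioning absorbs them).
#'
#' @param beta Coefficient vector (no intercept).
#' @param X Covariate matrix, one row per stratum member.
#' @param stratum Stratum identifier per row.
#' @param case Logical (or 0/1) indicator of the single case per stratum.
#' @return The conditional log-likelihood.
#' @export
conditional_loglik <- function(beta, X, stratum, case) {
  X <- as.matrix(X)
  if (!nrow(X)) stop("empty strata")
  eta <- drop(X %*% beta)
  sid <- as.integer(factor(stratum))
  m <- tapply(eta, sid, max)
  lse <- m + log(tapply(exp(eta - m[sid]), sid, sum))
  sum(eta[as.logical(case)]) - sum(lse)
}

#' Fit conditional logistic regression on matched strata
#'
#' Newton-Raphson maximization of the conditional likelihood of a matched
#' case-control design (one case per stratum), with monotone step-halving
#' and convergence on the gradient norm. Standard errors come from the
#' inverse observed information at the optimum; per-variable p-values are
#' Wald, `(beta/se)^2` against chi-square with 1 df. There is no intercept:
#' it is absorbed by the conditioning, as are the matching factors (age,
#' gender, smoking), which are deliberately not entered as regressors.
#'
#' @param data Matched data frame (e.g. from [match_controls()]) containing
#'   the selected variables, a stratum column and a `group` column.
#' @param variables Names of the amino-acid columns to include.
#' @param stratum Name of the stratum column (default `"stratum_id"`).
#' @param tol Gradient-norm convergence tolerance (default 1e-8).
#' @param maxit Maximum Newton iterations (default 100).
#' @return Object of class `aa_clogit`: `coefficients` (log-odds per
#'   micromolar), `se`, `wald_p`, `vcov`, `loglik`, `loglik_null`,
#'   `converged`, `iterations`, `n_strata`, `variables`.
#' @seealso [discriminant_score()], [predict.aa_clogit()]
#' @export
#' @examples
#' cfg <- default_generator_config()
#' cases <- generate_cohort(cfg, "case", 30, seed = 1)
#' pool <- generate_cohort(cfg, "control", 900, seed = 2)
#' m <- match_controls(cases, pool, seed = 3)
#' fit <- fit_conditional(m, c("Ala", "Ile", "Orn"))
#' coef(fit)
fit_conditional <- function(data, variables, stratum = "stratum_id",
                            tol = 1e-8, maxit = 100L) {
  missing_v <- setdiff(variables, names(data))
  if (length(missing_v))
    stop("missing selected amino acid(s): ",
         paste(missing_v, collapse = ", "))
  X <- as.matrix(data[, variables, drop = FALSE])
  sid <- as.integer(factor(data[[stratum]]))
  case <- as.logical(data$group == "case")
  if (any(tapply(case, sid, sum) != 1L))
    stop("each stratum must contain exactly one case")
  if (any(tapply(case, sid, length) < 2L))
    stop("each stratum must have at least 2 members")
  # a covariate constant within every stratum carries no information
  wvar <- vapply(seq_len(ncol(X)), function(j)
    sum(tapply(X[, j], sid, stats::var)), numeric(1))
  dead <- which(wvar == 0)
  if (length(dead))
    stop("no within-stratum information for: ",
         paste(variables[dead], collapse = ", "))

  idx <- split(seq_along(sid), sid)
  p <- ncol(X)
  beta <- numeric(p)
  ll <- conditional_loglik(beta, X, sid, case)
  converged <- FALSE; it <- 0L
  H <- NULL
  grad_hess <- function(beta) {
    eta <- drop(X %*% beta)
    g <- numeric(p); Hm <- matrix(0, p, p)
    for (ii in idx) {
      e <- eta[ii]
      w <- exp(e - max(e)); w <- w / sum(w)
      xb <- colSums(X[ii, , drop = FALSE] * w)
      g <- g + X[ii, , drop = FALSE][which(case[ii]), ] - xb
      Hm <- Hm + crossprod(X[ii, , drop = FALSE] * w,
                           X[ii, , drop = FALSE]) - tcrossprod(xb)
    }
    list(g = g, H = Hm)
  }
  while (it < maxit) {
    it <- it + 1L
    gh <- grad_hess(beta)
    if (sqrt(sum(gh$g^2)) < tol) { converged <- TRUE; H <- gh$H; break }
    step <- tryCatch(solve(gh$H, gh$g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    lam <- 1
    repeat {
      cand <- beta + lam * step
      ll_new <- conditional_loglik(cand, X, sid, case)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-10) break
    }
    if (lam < 1e-10) break
    beta <- cand; ll <- ll_new
    H <- gh$H
  }
  if (converged && !is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (is.null(V)) { converged <- FALSE; V <- matrix(NA_real_, p, p) }
  } else V <- matrix(NA_real_, p, p)
  se <- sqrt(diag(V))
  names(beta) <- names(se) <- variables
  dimnames(V) <- list(variables, variables)
  wald_p <- stats::pchisq((beta / se)^2, df = 1, lower.tail = FALSE)
  structure(list(coefficients = beta, se = se, wald_p = wald_p, vcov = V,
                 loglik = ll,
                 loglik_null = conditional_loglik(numeric(p), X, sid, case),
                 converged = converged, iterations = it,
                 n_strata = length(idx), variables = variables),
            class = "aa_clogit")
}

#' Discriminant score of subjects under a fitted conditional model
#'
#' The score of a subject is the linear predictor `x' beta` over the
#' selected amino acids — the logit of the conditional-logistic function
#' value `1/(1 + exp(-x' beta))`. It applies identically to study subjects,
#' independent test subjects and other patient groups.
#'
#' @param fit An `aa_clogit` object.
#' @param newdata Data frame carrying the selected amino-acid columns.
#' @return Numeric vector of unitless log-odds scores.
#' @export
discriminant_score <- function(fit, newdata) {
  stopifnot(inherits(fit, "aa_clogit"))
  missing_v <- setdiff(fit$variables, names(newdata))
  if (length(missing_v))
    stop("missing selected amino acid(s): ",
         paste(missing_v, collapse = ", "))
  drop(as.matrix(newdata[, fit$variables, drop = FALSE]) %*%
         fit$coefficients)
}

#' @export
coef.aa_clogit <- function(object, ...) object$coefficients

#' @export
vcov.aa_clogit <- function(object, ...) object$vcov

#' @export
logLik.aa_clogit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            class = "logLik")
}

#' Predict method for conditional-logistic screening fits
#'
#' @param object An `aa_clogit` fit.
#' @param newdata Data frame with the selected amino-acid columns.
#' @param type `"score"` for the discriminant score (linear predictor) or
#'   `"prob"` for its inverse-logit.
#' @param ... Unused.
#' @return Numeric vector.
#' @export
predict.aa_clogit <- function(object, newdata,
                              type = c("score", "prob"), ...) {
  type <- match.arg(type)
  s <- discriminant_score(object, newdata)
  if (type == "prob") stats::plogis(s) else s
}

#' @export
confint.aa_clogit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$coefficients - z * object$se,
              object$coefficients + z * object$se)
  colnames(ci) <- sprintf("%.1f %%", c((1 - level) / 2,
                                       1 - (1 - level) / 2) * 100)
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
print.aa_clogit <- function(x, ...) {
  cat("Conditional logistic regression on", x$n_strata,
      "matched strata\n")
  if (!x$converged) cat("  WARNING: fit did not converge\n")
  print(round(x$coefficients, 5))
  invisible(x)
}

#' @export
summary.aa_clogit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               z = object$coefficients / object$se, `Pr(>|z|)` = object$wald_p)
  structure(list(coefficients = tab, loglik = object$loglik,
                 loglik_null = object$loglik_null,
                 n_strata = object$n_strata, converged = object$converged),
            class = "summary.aa_clogit")
}

#' @export
print.summary.aa_clogit <- function(x, ...) {
  cat("Conditional logistic regression (", x$n_strata, " strata)\n",
      sep = "")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("Conditional log-likelihood: %.3f (null %.3f)\n",
              x$loglik, x$loglik_null))
  if (!x$converged) cat("WARNING: fit did not converge\n")
  invisible(x)
}
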