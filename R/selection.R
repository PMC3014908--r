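#' Enumerate candidate amino-acid subsets
#'
#' All subsets of `1..k_max` variables out of `p`, each exactly once, in
#' (size, lexicographic) order.
#'
#' @param p Number of candidate variables.
#' @param k_max Largest subset size (1 <= k_max <= p).
#' @return List of integer vectors (indices into the variable pool).
#' @seealso [subset_count()]
#' @export
#' @examples
#' length(enumerate_subsets(4, 2))  # 10
enumerate_subsets <- function(p, k_max) {
  if (k_max < 1L || k_max > p) stop("'k_max' must be in 1..p")
  out <- vector("list", subset_count(p, k_max))
  i <- 0L
  for (k in seq_len(k_max)) {
    cmb <- utils::combn(p, k)
    for (j in seq_len(ncol(cmb))) {
      i <- i + 1L
      out[[i]] <- cmb[, j]
    }
  }
  out
}

#' @rdname enumerate_subsets
#' @export
subset_count <- function(p, k_max) {
  if (k_max < 1L || k_max > p) stop("'k_max' must be in 1..p")
  sum(choose(p, seq_len(k_max)))
}

#' Exhaustive best-subset search scored by cross-validated AIC
#'
#' The model-selection engine: every subset of at most `k_max` candidate
#' variables is fitted by unconditional logistic regression, its
#' leave-one-out out-of-fold probabilities are computed with [loocv_probs()]
#' and scored with [cv_aic()], and candidates are ranked by the criterion
#' (ascending; ties broken by smaller subset then lexicographic order;
#' non-convergent candidates last with an infinite criterion). The result is
#' independent of row order and of the number of workers.
#'
#' @param data Cohort `data.frame` with a `group` column (`"case"` /
#'   `"control"`) and the candidate variable columns.
#' @param variables Candidate variable pool (default the full 21-amino-acid
#'   panel).
#' @param k_max Largest subset size (default 6, i.e. "below seven").
#' @param workers Parallel workers for candidate evaluation (forked;
#'   default 1).
#' @param penalty Keep the `2(k+1)` penalty in the criterion (default TRUE;
#'   `FALSE` ranks by pure cross-validated deviance).
#' @param top Number of leading candidates to keep in the ranking table
#'   (default 50; the best subset is always exact).
#' @return Object of class `aa_search`: list with `table` (ranked
#'   `data.frame`: `subset`, `size`, `cv_aic`, `converged`), `best`
#'   (character vector of variable names), `best_fit` (full-data
#'   [fit_logistic()] result for the best subset), `n_candidates`, and the
#'   settings.
#' @export
exhaustive_search <- function(data, variables = amino_acids(), k_max = 6L,
                              workers = 1L, penalty = TRUE, top = 50L) {
  missing_v <- setdiff(variables, names(data))
  if (length(missing_v))
    stop("variables not in data: ", paste(missing_v, collapse = ", "))
  y <- as.integer(data$group == "case")
  if (sum(y) < 2L || sum(1 - y) < 2L)
    stop("need at least 2 subjects per class")
  X <- as.matrix(data[, variables, drop = FALSE])
  subsets <- enumerate_subsets(length(variables), k_max)

  score_one <- function(idx) {
    pr <- tryCatch(loocv_probs(X[, idx, drop = FALSE], y),
                   error = function(e) structure(NA_real_,
                                                 converged = FALSE))
    conv <- isTRUE(attr(pr, "converged"))
    crit <- if (conv) cv_aic(pr, y, length(idx), penalty = penalty) else Inf
    c(crit = crit, converged = as.numeric(conv))
  }
  res <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(subsets, score_one, mc.cores = workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(subsets, score_one)
  }
  crit <- vapply(res, `[[`, numeric(1), "crit")
  conv <- vapply(res, `[[`, numeric(1), "converged") > 0
  if (all(!conv)) stop("search error: no candidate converged")

  subset_names <- vapply(subsets, function(i)
    paste(variables[i], collapse = "+"), character(1))
  sizes <- lengths(subsets)
  ord <- order(crit, sizes, subset_names)
  best_idx <- subsets[[ord[1]]]
  tab <- data.frame(subset = subset_names[ord], size = sizes[ord],
                    cv_aic = crit[ord], converged = conv[ord],
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = utils::head(tab, top),
                 best = variables[best_idx],
                 best_fit = fit_logistic(X[, best_idx, drop = FALSE], y),
                 n_candidates = length(subsets),
                 variables = variables, k_max = k_max, penalty = penalty),
            class = "aa_search")
}

#' @export
print.aa_search <- function(x, ...) {
  cat("Exhaustive subset search:", x$n_candidates, "candidates from",
      length(x$variables), "variables (k_max =", x$k_max, ")\n")
  cat("Best subset:", paste(x$best, collapse = " + "),
      sprintf("(cv AIC %.2f)\n", x$table$cv_aic[1]))
  cat("Leading candidates:\n")
  print(utils::head(x$table, 5))
  invisible(x)
}
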