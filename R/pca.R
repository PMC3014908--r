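#' Principal component analysis of standardized aminograms
#'
#' Eigen-decomposition of the correlation matrix implied by a standardized
#' concentration matrix (the population covariance of [standardize()]
#' output). Cases and controls are pooled for the decomposition; the group
#' labels are then used to compare each component's scores between groups
#' with the Mann-Whitney test. Each loading column is oriented so that its
#' largest-magnitude entry is positive.
#'
#' @param z Standardized matrix from [standardize()] (or any numeric matrix,
#'   which is standardized first). Must have at least as many rows as
#'   columns.
#' @param labels Group label per row, `"case"` or `"control"`.
#' @return An object of class `aa_pca`: list with `loadings` (variables x
#'   components, orthonormal), `eigenvalues` (non-increasing, summing to the
#'   number of variables), `scores` (subjects x components),
#'   `pc_pvalues`, and `correlation` (the decomposed matrix).
#' @export
aa_pca <- function(z, labels) {
  z <- as.matrix(z)
  if (is.null(attr(z, "scale"))) z <- standardize(z)
  n <- nrow(z); p <- ncol(z)
  if (n < p) stop("rank error: fewer rows (", n, ") than columns (", p, ")")
  if (length(labels) != n) stop("'labels' must have one entry per row")
  S <- crossprod(z) / n           # correlation matrix: unit diagonal
  e <- eigen(S, symmetric = TRUE)
  L <- e$vectors
  # sign convention: largest-|loading| entry of each column positive
  for (k in seq_len(p)) {
    j <- which.max(abs(L[, k]))
    if (L[j, k] < 0) L[, k] <- -L[, k]
  }
  dimnames(L) <- list(colnames(z), paste0("PC", seq_len(p)))
  scores <- z %*% L
  is_case <- labels == "case"
  pv <- vapply(seq_len(p), function(k)
    mann_whitney(scores[is_case, k], scores[!is_case, k])$p, numeric(1))
  structure(list(loadings = L, eigenvalues = e$values, scores = scores,
                 pc_pvalues = pv, correlation = S),
            class = "aa_pca")
}

#' @export
print.aa_pca <- function(x, ...) {
  p <- length(x$eigenvalues)
  kaiser <- sum(x$eigenvalues > 1)
  cat("PCA of standardized aminograms:", p, "components;",
      kaiser, "with eigenvalue > 1\n")
  show <- min(p, 6)
  tab <- rbind(eigenvalue = round(x$eigenvalues[1:show], 3),
               `p (case vs control)` = signif(x$pc_pvalues[1:show], 2))
  colnames(tab) <- paste0("PC", 1:show)
  print(tab)
  invisible(x)
}

#' Extract contributing amino acids from retained principal components
#'
#' Applies the retention-and-thresholding rule used to reduce the panel:
#' keep components with eigenvalue > 1 (Kaiser rule), among those keep the
#' components whose case-versus-control score comparison is significant
#' (`pc_pvalues < alpha`), and call a variable a contributor to a component
#' when its squared loading exceeds `variance_threshold`. Returns the
#' per-component contributor sets and their union (the reduced panel).
#'
#' @param pca An `aa_pca` object.
#' @param alpha Significance threshold on the per-component group test
#'   (default 0.05).
#' @param variance_threshold Squared-loading threshold (default 0.05, i.e.
#'   |loading| > 0.2236).
#' @return List with `retained` (component indices kept), `contributors`
#'   (named list of character vectors per kept component), and `panel`
#'   (sorted union, in panel order).
#' @export
extract_contributors <- function(pca, alpha = 0.05,
                                 variance_threshold = 0.05) {
  stopifnot(inherits(pca, "aa_pca"))
  retained <- which(pca$eigenvalues > 1)
  retained <- retained[pca$pc_pvalues[retained] < alpha]
  vars <- rownames(pca$loadings)
  contrib <- lapply(retained, function(k)
    vars[pca$loadings[, k]^2 > variance_threshold])
  names(contrib) <- colnames(pca$loadings)[retained]
  panel <- unique(unlist(contrib))
  panel <- vars[vars %in% panel]      # keep panel order
  list(retained = retained, contributors = contrib, panel = panel)
}
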