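#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples. The statistic is the number of
#' (x, y) pairs with x > y plus half the tied pairs. The two-sided p-value
#' comes from exhaustive enumeration of all group labelings when the smaller
#' sample has at most 8 observations (and the enumeration is tractable,
#' `choose(n, min) <= 2e5`), otherwise from the tie-corrected normal
#' approximation without continuity correction.
#'
#' @param x,y Numeric samples (non-empty).
#' @return A list with `U`, `p`, and `method` (`"exact"` or `"normal"`).
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$p  # 0.1 by enumeration
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  nx <- as.numeric(length(x)); ny <- as.numeric(length(y)); n <- nx + ny
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  exact_ok <- min(nx, ny) <= 8L && choose(n, min(nx, ny)) <= 2e5
  if (exact_ok) {
    combos <- utils::combn(n, nx)
    mid <- nx * ny / 2
    Us <- colSums(matrix(r[combos], nrow = nx)) - nx * (nx + 1) / 2
    p <- mean(abs(Us - mid) >= abs(U - mid) - 1e-12)
    method <- "exact"
  } else {
    t <- table(r)
    tie_term <- sum(t^3 - t) / (n * (n - 1))
    sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - nx * ny / 2) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal"
  }
  list(U = U, p = min(p, 1), method = method)
}

#' Standardize a concentration matrix
#'
#' Centers each column and divides by its population standard deviation
#' (the divide-by-n form), the transformation applied to aminograms before
#' principal component analysis. The result carries the column means and
#' scales as attributes `center` and `scale` (micromolar) so new subjects
#' can be projected with the same transformation. Applying the function to
#' its own output returns it unchanged.
#'
#' @param x Numeric matrix or data frame (subjects x amino acids).
#' @return Standardized numeric matrix with attributes `center` and `scale`.
#' @export
#' @examples
#' z <- standardize(cbind(a = c(1, 2, 3)))
#' z[, 1]  # -1.2247, 0, 1.2247
standardize <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("'x' must be numeric")
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 rows")
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  scl <- sqrt(colSums(xc^2) / n)
  degenerate <- which(scl == 0 | !is.finite(scl))
  if (length(degenerate))
    stop("degenerate (constant) column(s): ",
         paste(colnames(x)[degenerate] %||% degenerate, collapse = ", "))
  z <- sweep(xc, 2, scl, "/")
  attr(z, "center") <- ctr
  attr(z, "scale") <- scl
  z
}

#' Univariate amino-acid profile of cases versus controls
#'
#' Per-amino-acid group summary: case and control means and SDs, the
#' Mann-Whitney two-sided p-value, and the univariate ROC area oriented so
#' that it is at least 0.5.
#'
#' @param cases,controls Cohort data frames carrying all 21 amino-acid
#'   columns.
#' @return A `data.frame` with one row per amino acid: `mean_case`,
#'   `sd_case`, `mean_control`, `sd_control`, `p`, `auc`.
#' @export
summarize_amino_acids <- function(cases, controls) {
  for (aa in amino_acids()) {
    if (is.null(cases[[aa]]) || is.null(controls[[aa]]))
      stop("missing amino-acid column '", aa, "'")
  }
  rows <- lapply(amino_acids(), function(aa) {
    x <- cases[[aa]]; y <- controls[[aa]]
    a <- auc(x, y)
    data.frame(amino_acid = aa,
               mean_case = mean(x), sd_case = stats::sd(x),
               mean_control = mean(y), sd_control = stats::sd(y),
               p = mann_whitney(x, y)$p,
               auc = max(a, 1 - a))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- out$amino_acid
  out
}
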