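cohort_header <- function() {
  c("subject_id", "group", "age", "gender", "smoking", "bmi", "stage",
    "histology", amino_acids())
}

#' Read a cohort CSV
#'
#' Reads a subject table in the fixed cohort layout (`subject_id`, `group`,
#' `age`, `gender`, `smoking`, `bmi`, `stage`, `histology`, then the 21
#' amino-acid concentrations in panel order) and validates it: required
#' columns present (long-form amino-acid names are reported with their
#' canonical code), concentrations numeric and strictly positive, subject
#' ids unique, stage/histology `NA` exactly for controls. Unknown extra
#' columns are preserved.
#'
#' @param path Path to a CSV file.
#' @return A cohort `data.frame`.
#' @seealso [write_cohort()]
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  syn <- aa_synonyms()
  missing <- setdiff(cohort_header(), names(x))
  if (length(missing)) {
    hints <- vapply(missing, function(m) {
      alt <- names(syn)[syn == m]
      found <- intersect(alt, names(x))
      if (length(found))
        paste0(m, " (found '", found[1], "'; use the canonical code '", m,
               "')")
      else m
    }, character(1))
    stop("cohort file is missing required column(s): ",
         paste(hints, collapse = ", "))
  }
  validate_cohort(x, where = path)
  x
}

validate_cohort <- function(x, where = "cohort") {
  for (aa in amino_acids()) {
    v <- x[[aa]]
    if (!is.numeric(v))
      stop(where, ": column '", aa, "' is not numeric")
    bad <- which(!is.finite(v) | v <= 0)
    if (length(bad))
      stop(where, ": non-positive or missing concentration in column '", aa,
           "' at row(s) ", paste(utils::head(bad, 5), collapse = ", "))
  }
  dup <- which(duplicated(x$subject_id))
  if (length(dup))
    stop(where, ": duplicate subject_id at row(s) ",
         paste(utils::head(dup, 5), collapse = ", "))
  if (!all(x$group %in% c("case", "control")))
    stop(where, ": group must be 'case' or 'control'")
  ctrl <- x$group == "control"
  bad <- which((ctrl & (!is.na(x$stage) | !is.na(x$histology))) |
                 (!ctrl & (is.na(x$stage) | is.na(x$histology))))
  if (length(bad))
    stop(where, ": stage/histology must be NA exactly for controls; ",
         "violated at row(s) ", paste(utils::head(bad, 5), collapse = ", "))
  invisible(x)
}

#' Write a cohort CSV
#'
#' Writes a cohort `data.frame` in the fixed header order (extra columns
#' appended after the panel), UTF-8, `.` decimal separator. Reading the file
#' back with [read_cohort()] reproduces the records up to float formatting.
#'
#' @param x Cohort `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  extra <- setdiff(names(x), cohort_header())
  x <- x[, c(cohort_header(), extra), drop = FALSE]
  utils::write.csv(x, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @param scores Data frame of subject scores (`subject_id`, `group`,
#'   `score`).
#' @export
write_scores <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @param roc Data frame of ROC points as returned by [roc_curve()].
#' @export
write_roc <- function(roc, path) {
  utils::write.csv(roc, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
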