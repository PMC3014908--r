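#' Match controls to cases on gender, smoking status and age
#'
#' Greedy 1:m matching without replacement: cases are processed in an order
#' randomized by `seed`; for each case the eligible controls are the unused
#' pool subjects with the same gender and smoking category whose age differs
#' by at most `caliper` years, and the `ratio` nearest in age are taken (age
#' ties broken by a seeded random draw). Each selected set of one case plus
#' its controls forms one stratum for conditional logistic regression.
#'
#' Subjects with missing gender or smoking status are excluded up front with
#' a warning. If any case has fewer than `ratio` eligible controls the whole
#' match fails with an error naming the case ids, unless
#' `allow_partial = TRUE`, in which case those cases are dropped with a
#' warning.
#'
#' @param cases Cohort `data.frame` of cases.
#' @param pool Cohort `data.frame` of candidate controls, disjoint from
#'   `cases`.
#' @param ratio Controls per case, m >= 1 (default 3).
#' @param caliper Maximum |age difference| in years (default 5).
#' @param seed Integer seed controlling case order and tie-breaks.
#' @param allow_partial Drop unmatchable cases instead of failing.
#' @return A `data.frame` of class `aa_matched`: the matched cases and
#'   controls with a `stratum_id` column (case first within each stratum).
#'   Attributes `ratio` and `caliper` record the settings.
#' @export
#' @examples
#' cfg <- default_generator_config()
#' cases <- generate_cohort(cfg, "case", 20, seed = 1)
#' pool <- generate_cohort(cfg, "control", 600, seed = 2)
#' m <- match_controls(cases, pool, ratio = 3, caliper = 5, seed = 3)
#' table(m$group)
match_controls <- function(cases, pool, ratio = 3L, caliper = 5,
                           seed = 1L, allow_partial = FALSE) {
  if (ratio < 1L) stop("'ratio' must be >= 1")
  if (caliper < 0) stop("'caliper' must be >= 0")
  if (any(cases$subject_id %in% pool$subject_id))
    stop("'pool' must be disjoint from 'cases'")
  drop_missing <- function(x, what) {
    bad <- is.na(x$gender) | is.na(x$smoking) | x$gender == "" |
      x$smoking == ""
    if (any(bad)) {
      warning(sum(bad), " ", what,
              " excluded from matching (missing gender/smoking)")
      x <- x[!bad, , drop = FALSE]
    }
    x
  }
  cases <- drop_missing(cases, "case(s)")
  pool <- drop_missing(pool, "pool subject(s)")

  local_seed(substream_seed(seed, "matching"), {
    order_cases <- sample.int(nrow(cases))
    used <- rep(FALSE, nrow(pool))
    pick <- vector("list", nrow(cases))
    failed <- character(0)
    for (ci in order_cases) {
      cs <- cases[ci, ]
      elig <- which(!used & pool$gender == cs$gender &
                      pool$smoking == cs$smoking &
                      abs(pool$age - cs$age) <= caliper)
      if (length(elig) < ratio) {
        failed <- c(failed, cs$subject_id)
        next
      }
      d <- abs(pool$age[elig] - cs$age)
      # nearest age first; ties broken by a seeded random draw
      sel <- elig[order(d, sample.int(length(elig)))][seq_len(ratio)]
      used[sel] <- TRUE
      pick[[ci]] <- sel
    }
    if (length(failed)) {
      msg <- paste0(length(failed), " case(s) without ", ratio,
                    " eligible controls: ",
                    paste(utils::head(sort(failed), 10), collapse = ", "))
      if (!allow_partial) stop("matching failure: ", msg)
      warning("dropped ", msg)
    }
    kept <- which(!vapply(pick, is.null, logical(1)))
    if (!length(kept)) {
      res <- cbind(stratum_id = integer(0), cases[0, , drop = FALSE])
      attr(res, "ratio") <- as.integer(ratio)
      attr(res, "caliper") <- caliper
      class(res) <- c("aa_matched", "data.frame")
      return(res)
    }
    out <- vector("list", length(kept))
    for (k in seq_along(kept)) {
      ci <- kept[k]
      stratum <- rbind(cases[ci, , drop = FALSE],
                       pool[pick[[ci]], , drop = FALSE])
      stratum <- cbind(stratum_id = k, stratum)
      out[[k]] <- stratum
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    attr(res, "ratio") <- as.integer(ratio)
    attr(res, "caliper") <- caliper
    class(res) <- c("aa_matched", "data.frame")
    res
  })
}

#' Standardized mean difference of a covariate between cases and controls
#'
#' @param matched An `aa_matched` data frame.
#' @param var Column name (default `"age"`).
#' @return The absolute standardized mean difference
#'   |mean_case - mean_control| / sqrt((var_case + var_control)/2).
#' @export
matched_smd <- function(matched, var = "age") {
  x <- matched[[var]][matched$group == "case"]
  y <- matched[[var]][matched$group == "control"]
  abs(mean(x) - mean(y)) / sqrt((stats::var(x) + stats::var(y)) / 2)
}

#' @export
print.aa_matched <- function(x, ...) {
  ns <- length(unique(x$stratum_id))
  cat("Matched case-control strata: ", ns, " strata, 1:",
      attr(x, "ratio"), " ratio, age caliper ", attr(x, "caliper"),
      " y\n", sep = "")
  cat("  cases:", sum(x$group == "case"),
      " controls:", sum(x$group == "control"),
      " age SMD:", format(round(matched_smd(x), 3)), "\n")
  invisible(x)
}
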