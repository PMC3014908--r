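#' Canonical amino-acid panel
#'
#' Returns the ordered names of the 21 plasma free amino acids measured in
#' the screening panel, using the conventional three-letter codes (plus
#' `ABA` for alpha-aminobutyric acid and `Cit`/`Orn` for the non-proteinogenic
#' urea-cycle intermediates citrulline and ornithine). All cohort tables and
#' generator parameter vectors use this order.
#'
#' @return Character vector of length 21.
#' @export
#' @examples
#' amino_acids()
amino_acids <- function() {
  c("Thr", "Ser", "Asn", "Glu", "Gln", "Pro", "Gly", "Ala", "Cit", "ABA",
    "Val", "Met", "Ile", "Leu", "Tyr", "Phe", "His", "Trp", "Orn", "Lys",
    "Arg")
}

# synonym map for common long-form column names -> canonical codes
aa_synonyms <- function() {
  c(Threonine = "Thr", Serine = "Ser", Asparagine = "Asn", Glutamate = "Glu",
    "Glutamic acid" = "Glu", Glutamine = "Gln", Proline = "Pro",
    Glycine = "Gly", Alanine = "Ala", Citrulline = "Cit",
    "alpha-Aminobutyric acid" = "ABA", "2-Aminobutyric acid" = "ABA",
    Valine = "Val", Methionine = "Met", Isoleucine = "Ile", Leucine = "Leu",
    Tyrosine = "Tyr", Phenylalanine = "Phe", Histidine = "His",
    Tryptophan = "Trp", Ornithine = "Orn", Lysine = "Lys", Arginine = "Arg")
}

#' Default synthetic-cohort generator configuration
#'
#' Builds the generator configuration used throughout the package: group-wise
#' amino-acid means and standard deviations (in micromolar) for lung-cancer
#' patients and healthy controls, demographic margins (gender, smoking
#' status, age, BMI), stage and histology margins for patients, and a block
#' correlation structure among the amino acids.
#'
#' The marginal means/SDs are the published group summaries of the study
#' cohorts (141 patients, 423 matched controls). The correlation structure is
#' not published; the default uses biologically motivated blocks — the
#' branched-chain amino acids (Val, Ile, Leu) at rho 0.7, the aromatic amino
#' acids (Tyr, Phe, Trp) at rho 0.5, the urea-cycle intermediates (Cit, Orn,
#' Arg) at rho 0.4 — over a baseline inter-analyte correlation of 0.2, shared
#' by both groups. Subjects with unknown smoking status are not generated:
#' the smoking margins are renormalized over never/ex/current.
#'
#' @return An object of class `aa_config`: a list with components
#'   `amino_acids`, `mean_case`, `sd_case`, `mean_control`, `sd_control`
#'   (named numeric vectors, micromolar), `correlation` (blocks + baseline),
#'   `demographics` (per-group gender/smoking probabilities and age/BMI
#'   normal parameters, age with a truncation range), `stage_margins`,
#'   `histology_margins`, `n_cases`, `n_control_pool`, `seed`.
#' @seealso [build_covariance()], [generate_cohort()]
#' @export
#' @examples
#' cfg <- default_generator_config()
#' cfg$mean_case[["Ile"]]
default_generator_config <- function() {
  aa <- amino_acids()
  # columns: case mean, case sd, control mean, control sd (micromolar)
  tab <- matrix(c(
    115.6, 28.6, 115.9, 25.4,   # Thr
    117.1, 19.9, 111.4, 17.9,   # Ser
     45.1,  8.2,  44.8,  7.2,   # Asn
     46.7, 19.4,  45.7, 19.5,   # Glu
    580.5, 93.3, 587.9, 83.5,   # Gln
    168.0, 43.6, 150.9, 41.4,   # Pro
    263.6, 63.2, 237.0, 57.3,   # Gly
    422.3, 97.4, 383.7, 88.9,   # Ala
     34.4, 10.6,  33.2,  8.3,   # Cit
     24.2,  8.4,  23.2,  6.9,   # ABA
    244.8, 47.5, 239.8, 46.1,   # Val
     29.4,  6.1,  28.0,  5.2,   # Met
     84.3, 22.1,  69.7, 17.5,   # Ile
    131.8, 34.3, 122.4, 27.6,   # Leu
     80.7, 15.6,  75.8, 15.5,   # Tyr
     67.9, 12.2,  63.9, 11.2,   # Phe
     77.3, 15.0,  80.8, 10.7,   # His
     59.3, 12.0,  59.8, 10.9,   # Trp
     67.6, 19.7,  54.4, 12.3,   # Orn
    211.5, 36.2, 200.3, 34.1,   # Lys
    101.3, 21.6,  98.1, 17.8),  # Arg
    ncol = 4, byrow = TRUE,
    dimnames = list(aa, c("mean_case", "sd_case", "mean_control",
                          "sd_control")))

  cfg <- list(
    amino_acids  = aa,
    mean_case    = tab[, "mean_case"],
    sd_case      = tab[, "sd_case"],
    mean_control = tab[, "mean_control"],
    sd_control   = tab[, "sd_control"],
    correlation = list(
      blocks = list(
        bcaa       = list(members = c("Val", "Ile", "Leu"), rho = 0.7),
        aromatic   = list(members = c("Tyr", "Phe", "Trp"), rho = 0.5),
        urea_cycle = list(members = c("Cit", "Orn", "Arg"), rho = 0.4)),
      baseline = 0.2),
    demographics = list(
      case = list(
        gender  = c(male = 93, female = 48) / 141,
        smoking = c(never = 42, ex = 15, current = 79) / 136,
        age     = list(mean = 62.7, sd = 9.2, range = c(34, 83)),
        bmi     = list(mean = 22.6, sd = 2.8)),
      control = list(
        gender  = c(male = 279, female = 144) / 423,
        smoking = c(never = 126, ex = 45, current = 237) / 408,
        age     = list(mean = 61.1, sd = 8.7, range = c(32, 82)),
        bmi     = list(mean = 23.0, sd = 3.1))),
    stage_margins = c(I = 69, II = 8, III = 39, IV = 25) / 141,
    histology_margins = c(adenocarcinoma = 100, squamous = 36, other = 4) / 140,
    n_cases = 141L,
    n_control_pool = 4000L,
    seed = 1L)
  class(cfg) <- "aa_config"
  validate_config(cfg)
  cfg
}

#' Validate a generator configuration
#'
#' Checks the structural invariants of an [`aa_config`][default_generator_config]
#' object: positive means and SDs, categorical margins summing to one, and a
#' symmetric positive-definite implied correlation matrix.
#'
#' @param config An `aa_config` object.
#' @return `config`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "aa_config"))
  aa <- config$amino_acids
  if (length(aa) < 2L || anyDuplicated(aa))
    stop("amino_acids must be distinct names")
  for (f in c("mean_case", "sd_case", "mean_control", "sd_control")) {
    v <- config[[f]]
    if (!all(aa %in% names(v)))
      stop("field '", f, "' must be named by every amino acid")
    if (any(!is.finite(v[aa])) || any(v[aa] <= 0))
      stop("field '", f, "' must be strictly positive and finite")
  }
  sums1 <- function(p, what) {
    if (abs(sum(p) - 1) > 1e-9)
      stop(what, " margins must sum to 1 (got ", format(sum(p)), ")")
  }
  for (g in c("case", "control")) {
    d <- config$demographics[[g]]
    sums1(d$gender, paste(g, "gender"))
    sums1(d$smoking, paste(g, "smoking"))
    if (d$age$sd <= 0 || d$bmi$sd <= 0) stop(g, " age/bmi SD must be > 0")
  }
  sums1(config$stage_margins, "stage")
  sums1(config$histology_margins, "histology")
  for (b in names(config$correlation$blocks)) {
    blk <- config$correlation$blocks[[b]]
    if (!all(blk$members %in% aa))
      stop("correlation block '", b, "' names unknown amino acids")
    k <- length(blk$members)
    # equicorrelated block is PD iff -1/(k-1) < rho < 1
    if (blk$rho >= 1 || blk$rho <= -1 / (k - 1))
      stop("correlation block '", b, "' is not positive definite (rho = ",
           blk$rho, ")")
  }
  R <- correlation_matrix(config)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("implied correlation matrix is not positive definite ",
         "(min eigenvalue ", format(min(ev)), "); check blocks ",
         paste(names(config$correlation$blocks), collapse = ", "),
         " against the baseline correlation")
  invisible(config)
}

# assemble the block correlation matrix R
correlation_matrix <- function(config) {
  aa <- config$amino_acids
  p <- length(aa)
  R <- matrix(config$correlation$baseline, p, p, dimnames = list(aa, aa))
  for (blk in config$correlation$blocks) {
    idx <- match(blk$members, aa)
    R[idx, idx] <- blk$rho
  }
  diag(R) <- 1
  R
}

#' Group covariance matrix implied by a generator configuration
#'
#' Computes `D %*% R %*% D` where `D` is the diagonal matrix of the group's
#' amino-acid standard deviations and `R` the block correlation matrix of the
#' configuration. Units are micromolar squared.
#'
#' @param config An `aa_config` object.
#' @param group `"case"` or `"control"`.
#' @return A symmetric positive-definite 21 x 21 matrix with amino-acid
#'   dimnames.
#' @export
#' @examples
#' S <- build_covariance(default_generator_config(), "control")
#' S["Ile", "Ile"]  # 17.5^2
build_covariance <- function(config, group = c("case", "control")) {
  group <- match.arg(group)
  validate_config(config)
  sd <- if (group == "case") config$sd_case else config$sd_control
  sd <- sd[config$amino_acids]
  R <- correlation_matrix(config)
  S <- R * tcrossprod(sd)
  dimnames(S) <- list(config$amino_acids, config$amino_acids)
  S
}

# First-order analytic bound on the truncation bias of the kept-sample mean
# caused by rejecting draws with any non-positive coordinate.  Coordinate k
# is non-positive with probability p_k = Phi(-mu_k/sd_k); such rows sit
# lambda(alpha_k) = phi/Phi(-alpha_k) SDs below mu_k on coordinate k and
# rho_jk * lambda SDs below mu_j on coordinate j, so removing them lifts the
# kept mean of j by at most sum_k p_k * |rho_jk| * lambda_k * sd_j / (1 - r).
truncation_bias_bound <- function(config, group = c("case", "control")) {
  group <- match.arg(group)
  mu <- if (group == "case") config$mean_case else config$mean_control
  sd <- if (group == "case") config$sd_case else config$sd_control
  aa <- config$amino_acids
  mu <- mu[aa]; sd <- sd[aa]
  alpha <- mu / sd
  p <- stats::pnorm(-alpha)
  lambda <- stats::dnorm(alpha) / stats::pnorm(-alpha)
  R <- correlation_matrix(config)
  r_tot <- sum(p)
  bound <- as.vector(abs(R) %*% (p * lambda)) * sd / (1 - min(r_tot, 0.5))
  names(bound) <- aa
  bound
}

#' @export
print.aa_config <- function(x, ...) {
  cat("Aminogram generator configuration (", length(x$amino_acids),
      " amino acids)\n", sep = "")
  cat("  cases: n =", x$n_cases, " control pool: n =", x$n_control_pool, "\n")
  blocks <- vapply(names(x$correlation$blocks), function(b) {
    blk <- x$correlation$blocks[[b]]
    sprintf("%s{%s} rho=%.2f", b, paste(blk$members, collapse = ","), blk$rho)
  }, character(1))
  cat("  correlation blocks:", paste(blocks, collapse = "; "),
      "| baseline", x$correlation$baseline, "\n")
  cat("  concentration targets (uM), first rows:\n")
  print(utils::head(data.frame(mean_case = x$mean_case, sd_case = x$sd_case,
                               mean_control = x$mean_control,
                               sd_control = x$sd_control), 5))
  invisible(x)
}
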