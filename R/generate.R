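#' Generate a synthetic cohort of subjects with aminograms
#'
#' Draws `n` subjects of one group from the generator configuration.
#' Aminograms are multivariate normal with the group's mean vector and the
#' covariance from [build_covariance()]; any draw with a non-positive
#' concentration is rejected and redrawn, so all concentrations are strictly
#' positive. Demographics (gender, smoking, age, BMI) are sampled
#' independently from the group's margins, age truncated to the configured
#' range by resampling; stage and histology are sampled for cases and `NA`
#' for controls. The draw is deterministic given `seed` and does not disturb
#' the caller's RNG state.
#'
#' @param config An [`aa_config`][default_generator_config] object.
#' @param group `"case"` or `"control"`.
#' @param n Number of subjects (>= 1).
#' @param seed Integer seed for this draw.
#' @param id_prefix Prefix for `subject_id` (default the group name); ids are
#'   `<prefix>_00001`, ...
#' @return A `data.frame` with columns `subject_id`, `group`, `age`,
#'   `gender`, `smoking`, `bmi`, `stage`, `histology`, then the 21 amino-acid
#'   concentrations (micromolar) in panel order.
#' @export
#' @examples
#' ctrl <- generate_cohort(default_generator_config(), "control", 50, seed = 1)
#' colMeans(ctrl[, amino_acids()])[1:3]
generate_cohort <- function(config, group = c("case", "control"), n,
                            seed = config$seed, id_prefix = NULL) {
  group <- match.arg(group)
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    stop("'n' must be a positive count")
  n <- as.integer(n)
  validate_config(config)
  mu <- (if (group == "case") config$mean_case else
           config$mean_control)[config$amino_acids]
  Sigma <- build_covariance(config, group)
  dem <- config$demographics[[group]]

  local_seed(seed, {
    X <- matrix(NA_real_, n, length(mu))
    have <- 0L; drawn <- 0L; rejected <- 0L
    while (have < n) {
      batch <- max(n - have, 32L)
      Z <- MASS::mvrnorm(batch, mu = mu, Sigma = Sigma)
      if (batch == 1L) Z <- matrix(Z, nrow = 1L)
      ok <- rowSums(Z <= 0) == 0L
      drawn <- drawn + batch
      rejected <- rejected + sum(!ok)
      keep <- which(ok)
      if (length(keep)) {
        take <- keep[seq_len(min(length(keep), n - have))]
        X[have + seq_along(take), ] <- Z[take, , drop = FALSE]
        have <- have + length(take)
      }
      if (drawn >= 1000L && rejected / drawn > 0.5)
        stop("degenerate marginals: rejection rate ",
             sprintf("%.0f%%", 100 * rejected / drawn),
             " over ", drawn, " draws")
    }
    colnames(X) <- config$amino_acids

    gender <- sample(names(dem$gender), n, replace = TRUE, prob = dem$gender)
    smoking <- sample(names(dem$smoking), n, replace = TRUE,
                      prob = dem$smoking)
    age <- stats::rnorm(n, dem$age$mean, dem$age$sd)
    bad <- which(age < dem$age$range[1] | age > dem$age$range[2])
    while (length(bad)) {
      age[bad] <- stats::rnorm(length(bad), dem$age$mean, dem$age$sd)
      bad <- bad[age[bad] < dem$age$range[1] | age[bad] > dem$age$range[2]]
    }
    bmi <- stats::rnorm(n, dem$bmi$mean, dem$bmi$sd)
    if (group == "case") {
      stage <- sample(names(config$stage_margins), n, replace = TRUE,
                      prob = config$stage_margins)
      histology <- sample(names(config$histology_margins), n, replace = TRUE,
                          prob = config$histology_margins)
    } else {
      stage <- rep(NA_character_, n)
      histology <- rep(NA_character_, n)
    }
    prefix <- id_prefix %||% group
    out <- data.frame(
      subject_id = sprintf("%s_%05d", prefix, seq_len(n)),
      group = group, age = age, gender = gender, smoking = smoking,
      bmi = bmi, stage = stage, histology = histology,
      stringsAsFactors = FALSE)
    cbind(out, as.data.frame(X))
  })
}
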