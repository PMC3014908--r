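#' Configuration for an end-to-end screening-analysis run
#'
#' Bundles the settings of [run_pipeline()]. Either cohort CSV paths
#' (`cases_path`, `pool_path`) or generator settings must be supplied — not
#' neither. All randomness (generation, matching order, tie-breaks) derives
#' from the single `seed` via named substreams.
#'
#' @param out_dir Output directory for run artifacts.
#' @param seed Master seed.
#' @param cases_path,pool_path Optional cohort CSVs; when `NULL` cohorts are
#'   generated from `generator`.
#' @param generator An [`aa_config`][default_generator_config]; `n_cases`
#'   and `n_control_pool` set the simulated sizes.
#' @param ratio,caliper Matching settings (see [match_controls()]).
#' @param variables Candidate variable pool for the subset search.
#' @param k_max,penalty,workers Search settings (see [exhaustive_search()]).
#' @param subgroups Patient annotations for subgroup ROC areas.
#' @return A validated list of class `aa_run_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            cases_path = NULL, pool_path = NULL,
                            generator = default_generator_config(),
                            ratio = 3L, caliper = 5,
                            variables = amino_acids(), k_max = 6L,
                            penalty = TRUE, workers = 1L,
                            subgroups = c("stage", "histology")) {
  if (is.null(cases_path) != is.null(pool_path))
    stop("provide both 'cases_path' and 'pool_path', or neither")
  if (is.null(cases_path) && is.null(generator))
    stop("either cohort paths or generator settings must be present")
  if (k_max > 6L)
    warning("k_max = ", k_max,
            " exceeds the default 'below seven' cap; honoring as given")
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 cases_path = cases_path, pool_path = pool_path,
                 generator = generator, ratio = as.integer(ratio),
                 caliper = caliper, variables = variables,
                 k_max = as.integer(k_max), penalty = penalty,
                 workers = as.integer(workers), subgroups = subgroups),
            class = "aa_run_config")
}

#' Run the screening analysis end-to-end
#'
#' Executes simulate (optional) -> match -> profile -> select -> conditional
#' fit -> score -> report, writing every intermediate artifact (cohort,
#' matched, profile, loadings, contributor, ranked-candidate, score and ROC
#' CSV/JSON files) under `config$out_dir`, plus `summary.json` with the
#' selected subset, its criterion value, the conditional coefficients and
#' p-values, the overall and subgroup ROC areas, and a provenance block
#' (config hash, seed, package version). Identical `(config, seed)` give a
#' byte-identical summary.
#'
#' @param config An [`aa_run_config`][pipeline_config] object.
#' @return The summary as a list, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "aa_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  seed <- config$seed

  if (is.null(config$cases_path)) {
    g <- config$generator
    cases <- step("simulate", generate_cohort(
      g, "case", g$n_cases, seed = substream_seed(seed, "generator")))
    pool <- step("simulate", generate_cohort(
      g, "control", g$n_control_pool,
      seed = substream_seed(seed, "generator") + 1L))
    write_cohort(cases, out("cases.csv"))
    write_cohort(pool, out("control_pool.csv"))
  } else {
    cases <- step("read", read_cohort(config$cases_path))
    pool <- step("read", read_cohort(config$pool_path))
  }

  matched <- step("match", match_controls(
    cases, pool, ratio = config$ratio, caliper = config$caliper,
    seed = seed))
  utils::write.csv(matched, out("matched.csv"), row.names = FALSE)
  controls <- matched[matched$group == "control",
                      setdiff(names(matched), "stratum_id"), drop = FALSE]
  controls <- as.data.frame(controls)

  profile <- step("profile", summarize_amino_acids(cases, controls))
  utils::write.csv(profile, out("profile.csv"), row.names = FALSE)
  z <- step("profile", standardize(
    rbind(cases, controls)[, amino_acids()]))
  pca <- step("profile", aa_pca(z, c(cases$group, controls$group)))
  utils::write.csv(
    data.frame(amino_acid = rownames(pca$loadings), round(pca$loadings, 4)),
    out("loadings.csv"), row.names = FALSE)
  contributors <- extract_contributors(pca)
  jsonlite::write_json(contributors, out("contributors.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  study <- rbind(cases, controls)
  search <- step("select", exhaustive_search(
    study, variables = config$variables, k_max = config$k_max,
    workers = config$workers, penalty = config$penalty))
  utils::write.csv(search$table, out("candidates.csv"), row.names = FALSE)

  fit <- step("fit", fit_conditional(matched, search$best))
  jsonlite::write_json(
    list(variables = fit$variables, beta = as.list(coef(fit)),
         se = as.list(fit$se), wald_p = as.list(fit$wald_p),
         converged = fit$converged),
    out("conditional_fit.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)

  s_case <- discriminant_score(fit, cases)
  s_ctrl <- discriminant_score(fit, controls)
  write_scores(data.frame(
    subject_id = c(cases$subject_id, controls$subject_id),
    group = c(cases$group, controls$group),
    score = c(s_case, s_ctrl)), out("scores.csv"))
  write_roc(roc_curve(s_case, s_ctrl), out("roc.csv"))
  sub <- step("report", subgroup_auc(fit, cases, controls,
                                     by = config$subgroups))
  utils::write.csv(sub, out("subgroup_auc.csv"), row.names = FALSE)

  cfg_for_hash <- config
  cfg_for_hash$out_dir <- NULL
  cfg_file <- out("run_config.json")
  jsonlite::write_json(cfg_for_hash, cfg_file, auto_unbox = TRUE,
                       digits = NA, force = TRUE, pretty = TRUE)
  summary <- list(
    provenance = list(
      config_hash = unname(tools::md5sum(cfg_file)),
      seed = seed,
      package = "aminoscreen",
      version = as.character(utils::packageVersion("aminoscreen"))),
    n_cases = nrow(cases), n_matched_controls = nrow(controls),
    selected_subset = search$best,
    cv_aic = search$table$cv_aic[1],
    conditional = list(beta = as.list(round(coef(fit), 10)),
                       wald_p = as.list(signif(fit$wald_p, 10)),
                       converged = fit$converged),
    auc_overall = auc(s_case, s_ctrl),
    subgroup_auc = sub,
    pca = list(eigenvalues = round(pca$eigenvalues, 10),
               retained = contributors$retained,
               panel = contributors$panel))
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(summary)
}
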