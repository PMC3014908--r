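test_that("default configuration carries the published group summaries", {
  cfg <- default_generator_config()
  expect_identical(cfg$amino_acids, amino_acids())
  expect_equal(cfg$mean_case[["Ile"]], 84.3)
  expect_equal(cfg$sd_case[["Ile"]], 22.1)
  expect_equal(cfg$mean_control[["Orn"]], 54.4)
  expect_equal(cfg$sd_control[["Orn"]], 12.3)
  expect_equal(cfg$mean_control[["His"]], 80.8)
  expect_equal(sum(cfg$stage_margins), 1, tolerance = 1e-12)
  expect_equal(sum(cfg$histology_margins), 1, tolerance = 1e-12)
  for (g in c("case", "control")) {
    expect_equal(sum(cfg$demographics[[g]]$gender), 1, tolerance = 1e-12)
    expect_equal(sum(cfg$demographics[[g]]$smoking), 1, tolerance = 1e-12)
  }
})

test_that("build_covariance is D R D with the block correlation structure", {
  cfg <- default_generator_config()
  S_ctrl <- build_covariance(cfg, "control")
  expect_equal(S_ctrl["Ile", "Ile"], 17.5^2)
  S_case <- build_covariance(cfg, "case")
  expect_equal(S_case["Val", "Ile"], 0.7 * 47.5 * 22.1, tolerance = 1e-9)
  expect_equal(S_case["Tyr", "Phe"], 0.5 * 15.6 * 12.2, tolerance = 1e-9)
  expect_equal(S_case["Thr", "Ser"], 0.2 * 28.6 * 19.9, tolerance = 1e-9)
  expect_true(isSymmetric(S_case))
  expect_gt(min(eigen(S_case, symmetric = TRUE)$values), 0)

  # independence case: baseline 0, no blocks -> diagonal
  cfg0 <- cfg
  cfg0$correlation <- list(blocks = list(), baseline = 0)
  D <- build_covariance(cfg0, "case")
  expect_equal(D, diag(cfg$sd_case^2) |>
                 `dimnames<-`(dimnames(D)), tolerance = 1e-12)
})

test_that("invalid configurations are rejected with informative errors", {
  cfg <- default_generator_config()
  bad <- cfg; bad$sd_case[["Ala"]] <- -1
  expect_error(validate_config(bad), "positive")
  bad <- cfg; bad$stage_margins <- c(I = 0.5, II = 0.3, III = 0.1, IV = 0.2)
  expect_error(validate_config(bad), "sum to 1")
  bad <- cfg; bad$correlation$blocks$bcaa$rho <- -0.9
  expect_error(validate_config(bad), "bcaa")
})

test_that("cohort generation is seed-deterministic and strictly positive", {
  cfg <- default_generator_config()
  a <- generate_cohort(cfg, "control", 5, seed = 11)
  b <- generate_cohort(cfg, "control", 5, seed = 11)
  expect_identical(a, b)
  c2 <- generate_cohort(cfg, "control", 5, seed = 12)
  expect_false(identical(a$Ala, c2$Ala))

  x <- generate_cohort(cfg, "case", 2000, seed = 1)
  expect_true(all(as.matrix(x[, amino_acids()]) > 0))
  expect_true(all(x$age >= 34 & x$age <= 83))
  expect_true(all(x$stage %in% c("I", "II", "III", "IV")))
  ctrl <- generate_cohort(cfg, "control", 50, seed = 1)
  expect_true(all(is.na(ctrl$stage)) && all(is.na(ctrl$histology)))
  expect_error(generate_cohort(cfg, "case", 0, seed = 1), "positive count")
})

test_that("degenerate marginals trip the rejection-rate guard", {
  cfg <- default_generator_config()
  cfg$mean_control <- cfg$sd_control * 0.05
  expect_error(generate_cohort(cfg, "control", 10, seed = 1),
               "degenerate marginals")
})

test_that("generator recovers its marginal means and SDs at n = 1e5", {
  cfg <- default_generator_config()
  n <- 1e5
  for (g in c("case", "control")) {
    x <- as.matrix(generate_cohort(cfg, g, n, seed = 42)[, amino_acids()])
    mu <- if (g == "case") cfg$mean_case else cfg$mean_control
    sd_t <- if (g == "case") cfg$sd_case else cfg$sd_control
    # tolerance: 4 SE plus the analytic first-order truncation-bias bound
    # of the rejection sampler (non-negligible only for Glu)
    bias <- aminoscreen:::truncation_bias_bound(cfg, g)
    m_obs <- colMeans(x)
    s_obs <- apply(x, 2, sd)
    expect_true(all(abs(m_obs - mu) <= 4 * sd_t / sqrt(n) + bias),
                label = paste(g, "means recovered"))
    expect_true(all(abs(s_obs - sd_t) <= 4 * sd_t / sqrt(2 * n) + 2 * bias),
                label = paste(g, "SDs recovered"))
  }
})

test_that("generator recovers the block correlation structure", {
  cfg <- default_generator_config()
  x <- as.matrix(generate_cohort(cfg, "case", 1e5, seed = 7)[, amino_acids()])
  R_emp <- cor(x)
  R_pop <- aminoscreen:::correlation_matrix(cfg)
  expect_lt(max(abs(R_emp - R_pop)), 0.03)
  expect_equal(R_emp["Val", "Ile"], 0.7, tolerance = 0.02)
})
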