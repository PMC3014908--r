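test_that("Mann-Whitney matches hand-enumerated and symmetric cases", {
  # fully separated tiny samples: U = 0, p = 2/20 by enumeration
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)
  expect_equal(r$method, "exact")

  # identical multisets: U = n^2/2, p = 1
  x <- c(1, 2, 2, 5)
  r <- mann_whitney(x, x)
  expect_equal(r$U, 16 / 2)
  expect_equal(r$p, 1)

  # swapping samples maps U -> nx*ny - U with identical p
  set.seed(1)
  a <- rnorm(6); b <- rnorm(9)
  r1 <- mann_whitney(a, b); r2 <- mann_whitney(b, a)
  expect_equal(r1$U + r2$U, length(a) * length(b))
  expect_equal(r1$p, r2$p)

  expect_error(mann_whitney(numeric(0), 1), "non-empty")
})

test_that("Mann-Whitney agrees with the exhaustive permutation oracle", {
  set.seed(42)
  for (rep in 1:20) {
    nx <- sample(2:5, 1); ny <- sample(2:5, 1)
    x <- sample(1:6, nx, replace = TRUE)   # integer values force ties
    y <- sample(1:6, ny, replace = TRUE)
    got <- mann_whitney(x, y)
    want <- perm_mw_oracle(x, y)
    expect_equal(got$U, want$U)
    expect_equal(got$p, want$p)
  }
})

test_that("large-sample branch reproduces the tie-corrected normal test", {
  set.seed(3)
  x <- round(rnorm(60, 1, 2), 1)
  y <- round(rnorm(80, 0, 2), 1)
  got <- mann_whitney(x, y)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(got$method, "normal")
  expect_equal(got$U, unname(ref$statistic))
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
})

test_that("study-scale group differences land where the table reports them", {
  cfg <- default_generator_config()
  hits_thr <- 0; hits_ile <- 0
  for (seed in 1:10) {
    cases <- generate_cohort(cfg, "case", 141, seed = seed)
    ctrls <- generate_cohort(cfg, "control", 423, seed = seed + 500)
    if (mann_whitney(cases$Thr, ctrls$Thr)$p > 0.05) hits_thr <- hits_thr + 1
    if (mann_whitney(cases$Ile, ctrls$Ile)$p < 0.001) hits_ile <- hits_ile + 1
  }
  expect_gte(hits_thr, 9)
  expect_gte(hits_ile, 9)
})

test_that("standardization uses the population SD and is idempotent", {
  z <- standardize(cbind(a = c(1, 2, 3)))
  expect_equal(attr(z, "center"), c(a = 2))
  expect_equal(attr(z, "scale"), c(a = sqrt(2 / 3)))
  expect_equal(unname(z[, 1]), c(-1, 0, 1) * sqrt(1.5), tolerance = 1e-12)

  set.seed(4)
  x <- matrix(rnorm(200, 50, 9), 50, 4,
              dimnames = list(NULL, c("w", "x", "y", "z")))
  z1 <- standardize(x)
  expect_equal(unname(colMeans(z1)), rep(0, 4), tolerance = 1e-10)
  expect_equal(unname(sqrt(colSums(z1^2) / nrow(z1))), rep(1, 4),
               tolerance = 1e-10)
  z2 <- standardize(z1)
  expect_equal(z2[, ], z1[, ], tolerance = 1e-12)  # values unchanged

  expect_error(standardize(cbind(Gly = rep(3, 5))), "Gly")
})

test_that("the univariate profile reports means, tests and oriented AUCs", {
  cfg <- default_generator_config()
  cases <- generate_cohort(cfg, "case", 120, seed = 1)
  ctrls <- generate_cohort(cfg, "control", 150, seed = 2)
  tab <- summarize_amino_acids(cases, ctrls)
  expect_identical(tab$amino_acid, amino_acids())
  expect_true(all(tab$auc >= 0.5))
  expect_true(all(tab$p >= 0 & tab$p <= 1))

  same <- summarize_amino_acids(cases, cases)
  expect_true(all(same$auc == 0.5))

  broken <- cases[, setdiff(names(cases), "Trp")]
  expect_error(summarize_amino_acids(broken, ctrls), "Trp")
})

test_that("empirical univariate AUC converges to the binormal closed form", {
  cfg <- default_generator_config()
  n <- 1e5
  cases <- generate_cohort(cfg, "case", n, seed = 31)
  ctrls <- generate_cohort(cfg, "control", n, seed = 32)
  for (aa in c("Ile", "Orn", "His", "Ala", "Thr")) {
    d <- cfg$mean_case[[aa]] - cfg$mean_control[[aa]]
    pop <- pnorm(abs(d) / sqrt(cfg$sd_case[[aa]]^2 + cfg$sd_control[[aa]]^2))
    emp <- auc(cases[[aa]], ctrls[[aa]])
    expect_equal(max(emp, 1 - emp), pop, tolerance = 0.01,
                 label = paste("binormal AUC for", aa))
  }
})
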