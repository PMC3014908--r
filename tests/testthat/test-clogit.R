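hand_strata <- function() {
  # stratum A: case x=1, controls 0,2,0; stratum B: case x=0, controls 1,0,1
  data.frame(
    stratum_id = rep(c("A", "B"), each = 4),
    group = rep(c("case", "control", "control", "control"), 2),
    x = c(1, 0, 2, 0, 0, 1, 0, 1))
}

test_that("conditional log-likelihood matches direct evaluation", {
  d <- hand_strata()
  direct <- function(b) {
    (1 * b - log(exp(b) + 1 + exp(2 * b) + 1)) +
      (0 - log(1 + exp(b) + 1 + exp(b)))
  }
  for (b in c(-2, -0.5, 0, 0.7, 3))
    expect_equal(conditional_loglik(b, d["x"], d$stratum_id,
                                    d$group == "case"),
                 direct(b), tolerance = 1e-12)

  # beta = 0: each stratum of size 4 contributes log(1/4)
  S <- 141
  d0 <- data.frame(stratum_id = rep(seq_len(S), each = 4),
                   group = rep(c("case", rep("control", 3)), S),
                   x = rnorm(4 * S))
  expect_equal(conditional_loglik(0, d0["x"], d0$stratum_id,
                                  d0$group == "case"),
               -S * log(4), tolerance = 1e-10)

  expect_error(conditional_loglik(0, matrix(nrow = 0, ncol = 1),
                                  integer(0), logical(0)), "empty")
})

test_that("stratum-constant covariate shifts change nothing", {
  d <- hand_strata()
  shift <- ifelse(d$stratum_id == "A", 100, -3)
  for (b in c(-1, 0.5, 2))
    expect_equal(conditional_loglik(b, d["x"], d$stratum_id,
                                    d$group == "case"),
                 conditional_loglik(b, d["x"] + shift, d$stratum_id,
                                    d$group == "case"),
                 tolerance = 1e-10)
  f1 <- fit_conditional(d, "x")
  d2 <- d; d2$x <- d2$x + shift
  f2 <- fit_conditional(d2, "x")
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
})

test_that("the conditional MLE matches a fine grid search", {
  d <- hand_strata()
  fit <- fit_conditional(d, "x")
  expect_true(fit$converged)
  grid <- seq(-10, 10, by = 1e-4)
  ll <- cond_ll_direct(grid, split(d$x, d$stratum_id),
                       case_pos = c(1, 1))
  expect_equal(unname(coef(fit)), grid[which.max(ll)], tolerance = 1e-4)
  expect_gte(fit$loglik, fit$loglik_null)
})

test_that("fits agree with the survival-package conditional likelihood", {
  withr::local_package("survival")
  d <- simulate_strata(150, m = 3, beta = 0.8, seed = 2)
  fit <- fit_conditional(d, "x")
  ref <- survival::clogit(
    I(group == "case") ~ x + strata(stratum_id), data = d)
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-6)
  expect_equal(fit$loglik, ref$loglik[2], tolerance = 1e-6)
})

test_that("known coefficients are recovered from simulated strata", {
  d <- simulate_strata(500, m = 3, beta = 1, seed = 10)
  fit <- fit_conditional(d, "x")
  expect_true(fit$converged)
  expect_lt(abs(coef(fit) - 1), 3 * fit$se)
})

test_that("1:1 matching reduces to the pair-difference logistic model", {
  d <- simulate_strata(80, m = 1, beta = 0.7, seed = 6)
  fit <- fit_conditional(d, "x")
  diffs <- tapply(seq_len(nrow(d)), d$stratum_id, function(ix) {
    d$x[ix][d$group[ix] == "case"] - d$x[ix][d$group[ix] == "control"]
  })
  ref <- glm(rep(1, length(diffs)) ~ 0 + unlist(diffs), family = binomial,
             control = glm.control(epsilon = 1e-12))
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-6)
})

test_that("degenerate strata are rejected with informative errors", {
  d <- hand_strata()
  d$flat <- ifelse(d$stratum_id == "A", 5, 9)   # stratum-constant covariate
  expect_error(fit_conditional(d, "flat"), "flat")
  d2 <- d; d2$group <- "control"
  expect_error(fit_conditional(d2, "x"), "exactly one case")
  expect_error(fit_conditional(d, c("x", "absent")), "absent")
})

test_that("discriminant scores are the linear predictor", {
  cfg <- default_generator_config()
  cases <- generate_cohort(cfg, "case", 60, seed = 1)
  pool <- generate_cohort(cfg, "control", 2000, seed = 2)
  m <- match_controls(cases, pool, seed = 3)
  six <- c("Ala", "Val", "Ile", "His", "Trp", "Orn")
  fit <- fit_conditional(m, six)
  s <- discriminant_score(fit, m)
  expect_equal(s, drop(as.matrix(m[, six]) %*% coef(fit)), tolerance = 1e-12)

  # homogeneity: doubling every coefficient doubles every score
  fit2 <- fit
  fit2$coefficients <- 2 * fit2$coefficients
  expect_equal(discriminant_score(fit2, m), 2 * s, tolerance = 1e-12)

  # zero coefficients give identically zero scores
  fit0 <- fit
  fit0$coefficients[] <- 0
  expect_true(all(discriminant_score(fit0, m) == 0))

  # cases score higher on average under the case-shifted generator
  expect_gt(mean(s[m$group == "case"]), mean(s[m$group == "control"]))

  expect_error(discriminant_score(fit, m[, c("Ala", "Val")]), "missing")
  expect_equal(predict(fit, m, type = "prob"), plogis(s), tolerance = 1e-12)
})
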