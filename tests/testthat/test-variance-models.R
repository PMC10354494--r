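# Variance partitioning, repeatability, R2, VIF, bootstrap, residuals.

test_that("model specs enforce the uninformed/informed structure", {
  u <- uninformed_spec("y")
  expect_equal(u$random, "colony_id")
  expect_length(u$fixed, 0)
  i <- informed_spec("y", c("temp_c_z"))
  expect_setequal(i$random, c("colony_id", "date"))
  expect_error(model_spec("y", random = "date"), "colony_id")
})

test_that("pure-noise data gives a near-zero colony variance", {
  d <- simulate_repeatability_data(10, 20, var_colony = 0, var_resid = 1,
                                   seed = 2L)
  vd <- fit_lmm(d, uninformed_spec("y"))
  expect_lt(vd$var_colony, 0.05)
  expect_lt(repeatability(vd), 0.05)
})

test_that("an exact linear response is recovered with tiny residual", {
  set.seed(3)
  d <- simulate_repeatability_data(6, 10, var_colony = 0.5, var_resid = 1,
                                   seed = 3L)
  d$x <- rnorm(nrow(d))
  d$y <- 2 + 3 * d$x + rnorm(nrow(d), 0, 1e-4)
  vd <- fit_lmm(d, informed_spec("y", "x"))
  b <- vd$beta$estimate[vd$beta$term == "x"]
  expect_equal(b, 3, tolerance = 1e-3)
  expect_lt(vd$var_resid, 1e-4)
})

test_that("closed-form balanced fit equals the lme4 REML solution", {
  for (seed in c(5, 6, 7)) {
    d <- simulate_repeatability_data(8, 12, var_colony = 0.7, var_resid = 1,
                                     seed = seed)
    a <- fit_lmm(d, uninformed_spec("y"), method = "anova")
    r <- fit_lmm(d, uninformed_spec("y"), method = "reml")
    expect_equal(a$var_colony, r$var_colony, tolerance = 1e-5)
    expect_equal(a$var_resid, r$var_resid, tolerance = 1e-5)
  }
  # boundary case: both truncate the colony variance to zero
  d0 <- simulate_repeatability_data(6, 30, var_colony = 0, var_resid = 1,
                                    seed = 41L)
  a0 <- fit_lmm(d0, uninformed_spec("y"), method = "anova")
  if (a0$singular) expect_equal(a0$var_colony, 0)
})

test_that("balanced fit matches the closed-form ANOVA oracle", {
  d <- simulate_repeatability_data(9, 7, var_colony = 2, var_resid = 1,
                                   seed = 10L)
  vd <- fit_lmm(d, uninformed_spec("y"))
  # independent method-of-moments computation
  fit_aov <- aov(y ~ Error(colony_id), data = transform(
    d, colony_id = factor(colony_id)))
  ms <- summary(fit_aov)
  msb <- ms[["Error: colony_id"]][[1]][["Mean Sq"]]
  msw <- ms[["Error: Within"]][[1]][["Mean Sq"]]
  expect_equal(vd$var_colony, (msb - msw) / 7, tolerance = 1e-10)
  expect_equal(vd$var_resid, msw, tolerance = 1e-10)
})

test_that("repeatability and R2 follow their variance-share definitions", {
  vd <- structure(list(var_colony = 1, var_date = 0, var_resid = 1,
                       var_fixed = 0), class = "variance_decomposition")
  expect_equal(repeatability(vd), 0.5)
  vd2 <- structure(list(var_colony = 0, var_date = 0.5, var_resid = 1,
                        var_fixed = 2), class = "variance_decomposition")
  expect_equal(repeatability(vd2), 0)
  expect_equal(repeatability(vd2, include_fixed = TRUE), 0)
  r2 <- r2_marginal_conditional(
    structure(list(var_colony = 1, var_date = 1, var_resid = 1,
                   var_fixed = 1), class = "variance_decomposition"))
  expect_equal(r2$r2_marginal, 0.25)
  expect_equal(r2$r2_conditional, 0.75)
  # identity: marginal + random share + residual share = 1
  resid_share <- 1 / 4
  expect_equal(r2$r2_marginal + (r2$r2_conditional - r2$r2_marginal) +
                 resid_share, 1)
  expect_error(repeatability(structure(
    list(var_colony = 0, var_date = 0, var_resid = 0, var_fixed = 0),
    class = "variance_decomposition")), "undefined")
})

test_that("known variance components are recovered in an informed design", {
  d <- simulate_repeatability_data(12, 30, var_colony = 2, var_date = 1,
                                   var_resid = 1, seed = 20L)
  vd <- fit_lmm(d, model_spec("y", random = c("colony_id", "date")))
  expect_equal(vd$var_colony, 2, tolerance = 1.2)
  expect_equal(vd$var_date, 1, tolerance = 0.8)
  expect_equal(vd$var_resid, 1, tolerance = 0.15)
  R <- repeatability(vd)
  expect_gt(R, 0.25)
  expect_lt(R, 0.75)
})

test_that("bootstrap CIs are deterministic, degenerate at B=1, honest", {
  d <- simulate_repeatability_data(8, 10, var_colony = 1, var_resid = 1,
                                   seed = 30L)
  spec <- uninformed_spec("y")
  e1 <- bootstrap_repeatability(d, spec, B = 50, seed = 9L)
  e2 <- bootstrap_repeatability(d, spec, B = 50, seed = 9L)
  expect_identical(e1$boot, e2$boot)
  expect_identical(c(e1$ci_low, e1$ci_high), c(e2$ci_low, e2$ci_high))
  b1 <- bootstrap_repeatability(d, spec, B = 1, seed = 4L)
  expect_equal(b1$ci_low, b1$ci_high)
  expect_equal(b1$ci_low, b1$boot[1])
  # stratified resampling keeps every colony at its original row count
  s <- bootstrap_repeatability(d, spec, B = 20, seed = 5L,
                               type = "stratified")
  expect_equal(s$n_failed, 0)
  expect_true(all(s$boot >= 0 & s$boot <= 1))
})

test_that("parametric bootstrap through lme4 also works for informed fits", {
  d <- simulate_repeatability_data(6, 8, var_colony = 1, var_date = 0.2,
                                   var_resid = 1, seed = 31L)
  d$x <- rnorm(nrow(d))
  est <- suppressWarnings(bootstrap_repeatability(
    d, informed_spec("y", "x"), B = 8, seed = 2L))
  expect_true(is.finite(est$R))
  expect_true(est$ci_low <= est$ci_high)
})

test_that("VIF matches the regression-definition oracle", {
  set.seed(8)
  n <- 120
  tab <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  tab$x3 <- 0.8 * tab$x1 + 0.6 * rnorm(n)
  v <- compute_vif(tab, c("x1", "x2", "x3"))
  # oracle: VIF_j = 1 / (1 - R2_j) from regressing each column on the rest
  X <- as.matrix(tab)
  for (j in 1:3) {
    r2 <- summary(lm(X[, j] ~ X[, -j]))$r.squared
    expect_equal(unname(v[j]), 1 / (1 - r2), tolerance = 1e-8)
  }
  expect_true(all(v >= 1))
  # near-orthogonal predictors sit near 1, near-collinear blow up
  expect_lt(v["x2"], 1.2)
  tab$x4 <- tab$x1 + rnorm(n, 0, 1e-4)
  expect_gt(compute_vif(tab, c("x1", "x4"))[["x1"]], 100)
  tab$x5 <- tab$x1
  expect_error(compute_vif(tab, c("x1", "x5")), "collinear")
})

test_that("VIF agrees with the car package on a mixed factor design", {
  skip_if_not_installed("car")
  set.seed(9)
  tab <- data.frame(x1 = rnorm(80), x2 = rnorm(80),
                    f = factor(sample(c("u", "v"), 80, TRUE)))
  tab$y <- rnorm(80)
  mine <- compute_vif(tab, c("x1", "x2", "f"))
  ref <- car::vif(lm(y ~ x1 + x2 + f, data = tab))
  expect_equal(unname(mine[c("x1", "x2")]), unname(ref[c("x1", "x2")]),
               tolerance = 1e-8)
})

test_that("partial residuals isolate the focal driver", {
  d <- simulate_repeatability_data(10, 15, var_colony = 1, var_date = 0.3,
                                   var_resid = 0.5, seed = 33L)
  set.seed(34)
  d$x1 <- rnorm(nrow(d))
  d$x2 <- rnorm(nrow(d))
  d$y <- d$y + 1.5 * d$x1 - 2 * d$x2
  vd <- fit_lmm(d, informed_spec("y", c("x1", "x2")))
  pr <- partial_residuals(d, vd, "x1")
  slope <- coef(lm(corrected ~ x1, data = pr))[["x1"]]
  b1 <- vd$beta$estimate[vd$beta$term == "x1"]
  expect_equal(slope, b1, tolerance = 0.05)
  # single-predictor model: corrected = y - random-effect predictions
  vd1 <- fit_lmm(d, informed_spec("y", "x1"))
  pr1 <- partial_residuals(d, vd1, "x1")
  re <- fitted(vd1$fit) -
    as.numeric(model.matrix(terms(vd1$fit, fixed.only = TRUE),
                            model.frame(vd1$fit)) %*% lme4::fixef(vd1$fit))
  expect_equal(pr1$corrected, unname(d$y - re), tolerance = 1e-10)
  expect_error(partial_residuals(d, vd1, "x9"), "not a fixed effect")
})

test_that("informed repeatability never exceeds uninformed when a
           colony-constant driver is confounded with colony identity", {
  for (seed in 1:8) {
    set.seed(seed + 600)
    w_c <- rnorm(12)
    d <- simulate_repeatability_data(12, 12, var_colony = 0.3,
                                     var_resid = 1, seed = seed + 700)
    w <- w_c[as.integer(factor(d$colony_id))]
    d$y <- d$y + 1.2 * w
    d$w <- w
    r_un <- repeatability(fit_lmm(d, uninformed_spec("y")))
    r_in <- suppressWarnings(
      repeatability(fit_lmm(d, informed_spec("y", "w"))))
    expect_lte(r_in, r_un + 1e-8)
  }
})
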