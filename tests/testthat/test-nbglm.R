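test_that("dispersion estimates are near zero for Poisson genes", {
  set.seed(31)
  d <- make_design()
  mm <- build_model_matrix(d)
  sf <- rep(1, 64)
  a_hat <- replicate(200, estimate_dispersion(rpois(64, 100), mm, sf))
  expect_gte(mean(a_hat <= 0.05), 0.95)
  expect_true(all(a_hat >= 1e-8))
})

test_that("dispersion estimates recover a true NB dispersion", {
  set.seed(32)
  d <- make_design()
  mm <- build_model_matrix(d)
  sf <- rep(1, 64)
  a_hat <- replicate(200,
    estimate_dispersion(rnbinom(64, mu = 100, size = 2), mm, sf))
  expect_gt(median(a_hat), 0.3)
  expect_lt(median(a_hat), 0.7)
})

test_that("underdispersed genes are clamped to the floor", {
  d <- make_design()
  mm <- build_model_matrix(d)
  y <- rep(100, 64)                     # zero variance: negative moment
  expect_equal(estimate_dispersion(y, mm, rep(1, 64), refine = FALSE), 1e-8)
  expect_lt(estimate_dispersion(y, mm, rep(1, 64)), 1e-6)
  expect_error(estimate_dispersion(rep(5, 8), build_model_matrix(
    make_design(replicates_per_cell = 1L)), rep(1, 8)), "degrees of freedom")
})

test_that("constant counts give a pure intercept fit", {
  d <- make_design()
  mm <- build_model_matrix(d)
  f <- fit_nb_glm(rep(64, 64), mm, rep(1, 64), alpha = 0.01)
  expect_true(f$converged)
  expect_equal(unname(f$beta["Intercept"]), 6, tolerance = 1e-8)
  expect_equal(max(abs(f$beta[-1])), 0, tolerance = 1e-8)
})

test_that("the two-group NB MLE equals the log-ratio of group means", {
  set.seed(41)
  d2 <- make_design(factors = "Salinity", replicates_per_cell = 16L)
  mm2 <- build_model_matrix(d2)
  sf <- rep(1, 32)
  y <- rnbinom(32, mu = 50, size = 5)
  y[y == 0] <- 1
  f <- fit_nb_glm(y, mm2, sf, alpha = 0.2)
  g <- d2$Salinity == "treated"
  # group-mean parameterisation: the NB score equation per group reduces
  # to mu = group mean when size factors are constant
  expect_equal(unname(f$beta["Salinity"]),
               log2(mean(y[g]) / mean(y[!g])), tolerance = 1e-6)
  expect_equal(unname(f$beta["Intercept"]), log2(mean(y[!g])),
               tolerance = 1e-6)
})

test_that("fits agree with an independent NB GLM implementation", {
  skip_if_not_installed("MASS")
  set.seed(43)
  d <- make_design()
  mm <- build_model_matrix(d)
  sf <- exp(rnorm(64, 0, 0.15))
  alpha <- 0.1
  for (i in 1:5) {
    mu <- sf * 2^(5 + mm[, "Salinity"] - 0.5 * mm[, "Salinity:Flow"])
    y <- rnbinom(64, mu = mu, size = 1 / alpha)
    f <- fit_nb_glm(y, mm, sf, alpha = alpha)
    ref <- suppressWarnings(glm(y ~ mm - 1 + offset(log(sf)),
               family = MASS::negative.binomial(theta = 1 / alpha)))
    expect_equal(unname(f$beta), unname(coef(ref)) / log(2),
                 tolerance = 1e-5)
    # fix the GLM dispersion at 1: theta already encodes the NB variance
    se_ref <- sqrt(diag(summary(ref, dispersion = 1)$cov.scaled))
    expect_equal(unname(f$se), unname(se_ref) / log(2), tolerance = 1e-3)
  }
})

test_that("a separated (all-zero cell) gene is clamped and flagged", {
  d <- make_design()
  mm <- build_model_matrix(d)
  y <- rep(100, 64)
  y[d$Salinity == "treated"] <- 0
  f <- fit_nb_glm(y, mm, rep(1, 64), alpha = 0.05)
  expect_true(f$flagged)
  expect_equal(unname(f$beta["Salinity"]), -10)
})

test_that("Wald tests convert z scores to two-sided normal p-values", {
  f <- list(beta = c(a = 0, b = 1.959964, c = 3), se = c(a = 1, b = 1, c = 1))
  wt <- wald_test(f)
  expect_equal(unname(wt$p["a"]), 1)
  expect_equal(unname(wt$p["b"]), 0.05, tolerance = 1e-6)
  expect_equal(unname(wt$p["c"]), 0.0026998, tolerance = 1e-4)
  expect_equal(unname(wald_test(f, "c")$z), 3)
  expect_error(wald_test(list(beta = c(x = 1), se = c(x = 0))), "zero")
  expect_error(wald_test(f, "nope"), "unknown term")
})

test_that("BH adjustment matches the hand example and a brute-force oracle", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(0.2), 0.2)
  expect_error(adjust_bh(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(61)
  for (i in 1:50) {
    p <- runif(sample(1:80, 1))^sample(1:3, 1)
    expect_equal(adjust_bh(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("shrinkage matches the conjugate closed form for one component", {
  set.seed(71)
  beta <- rnorm(200, 0, 1)
  se <- runif(200, 0.2, 0.5)
  tau <- 0.8
  sh <- shrink_lfc(beta, se, grid = c(0, tau), weights = c(0, 1))
  expect_equal(sh$posterior_mean, beta * tau^2 / (tau^2 + se^2),
               tolerance = 1e-8)
  # pure point mass at zero shrinks everything to zero
  sh0 <- shrink_lfc(beta, se, grid = c(0, tau), weights = c(1, 0))
  expect_equal(max(abs(sh0$posterior_mean)), 0)
})

test_that("shrinkage is adaptive and never increases magnitude", {
  set.seed(72)
  n <- 500
  null_idx <- 1:400
  beta_true <- c(rep(0, 400), rnorm(100, 0, 2))
  se <- runif(n, 0.1, 0.3)
  beta_hat <- beta_true + rnorm(n, 0, se)
  sh <- shrink_lfc(beta_hat, se)
  expect_true(all(abs(sh$posterior_mean) <= abs(beta_hat) + 1e-12))
  expect_equal(sum(sh$weights), 1, tolerance = 1e-8)
  # nulls shrink proportionally more than strong signals
  strong <- abs(beta_hat) > 1.5
  expect_lt(mean(abs(sh$posterior_mean[null_idx]) /
                   pmax(abs(beta_hat[null_idx]), 1e-6)),
            mean(abs(sh$posterior_mean[strong]) / abs(beta_hat[strong])))
  # tiny standard errors leave estimates nearly unshrunken
  sh_tiny <- shrink_lfc(beta_hat, rep(1e-5, n))
  expect_equal(sh_tiny$posterior_mean, beta_hat, tolerance = 1e-3)
})

test_that("shrinkage input validation", {
  expect_error(shrink_lfc(c(1, 2), c(1, -1)))
  expect_error(shrink_lfc(1, 1, grid = numeric(0)), "empty")
  expect_error(shrink_lfc(1, 1, grid = c(0.5, 1)), "point mass")
})

test_that("rescaling all size factors only shifts the intercept", {
  set.seed(81)
  d <- make_design()
  mm <- build_model_matrix(d)
  sf <- exp(rnorm(64, 0, 0.1))
  y <- rnbinom(64, mu = 100, size = 10) + 1
  f1 <- fit_nb_glm(y, mm, sf, alpha = 0.1)
  f2 <- fit_nb_glm(y, mm, 4 * sf, alpha = 0.1)
  expect_equal(unname(f2$beta["Intercept"]),
               unname(f1$beta["Intercept"]) - 2, tolerance = 1e-6)
  expect_equal(f1$beta[-1], f2$beta[-1], tolerance = 1e-6)
  expect_equal(f1$se, f2$se, tolerance = 1e-6)
})

test_that("per-term families are adjusted independently across genes", {
  res <- sim_study(150, seed = 19,
                   effects = effect_config(frac_de = 0.2,
                                           frac_interaction = 0))
  fit <- res$fit
  for (tm in colnames(fit$padj)) {
    expect_equal(unname(fit$padj[, tm]), unname(adjust_bh(fit$p[, tm])))
    expect_true(all(fit$padj[, tm] >= fit$p[, tm] - 1e-12, na.rm = TRUE))
  }
})
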