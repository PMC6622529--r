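sim_design <- function(n, beta = c(1, 2), seed = 1) {
  set.seed(seed)
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- 0.5 + beta[1] * x1 + beta[2] * x2 + rnorm(n)
  design_matrix(data.frame(y = y, x1 = x1, x2 = x2), "y", c("x1", "x2"))
}

test_that("standardization z-scores predictors and fixes the intercept at mean(y)", {
  d <- standardize_predictors(sim_design(200, seed = 4))
  expect_equal(colMeans(d$X[, -1]), c(x1 = 0, x2 = 0), tolerance = 1e-10)
  expect_equal(apply(d$X[, -1], 2, sd), c(x1 = 1, x2 = 1), tolerance = 1e-10)
  fit <- ols_fit(d)
  expect_equal(unname(fit$beta["(Intercept)"]), mean(d$y), tolerance = 1e-10)
  # idempotent
  expect_equal(standardize_predictors(d)$X, d$X, tolerance = 1e-12)
  # constant columns are named in the error
  bad <- design_matrix(data.frame(y = 1:5, k = rep(2, 5)), "y", "k")
  expect_error(standardize_predictors(bad), "k")
})

test_that("OLS matches closed forms, keeps residuals orthogonal to X", {
  d <- sim_design(300, seed = 7)
  fit <- ols_fit(d)
  ref <- lm(d$y ~ d$X[, -1])
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-10)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-10)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-8)
  expect_lt(max(abs(crossprod(d$X, fit$residuals))), 1e-8)
  # exact fit when y is linear in X
  d2 <- d; d2$y <- as.numeric(d$X %*% c(1, 2, 3))
  expect_equal(max(abs(ols_fit(d2)$residuals)), 0, tolerance = 1e-10)
  # rank deficiency is an error
  dd <- design_matrix(data.frame(y = rnorm(10), a = 1:10, b = 2 * (1:10)),
                      "y", c("a", "b"))
  expect_error(ols_fit(dd), "rank")
})

test_that("single-predictor OLS slope equals cov(x, y)/var(x)", {
  set.seed(12)
  x <- rnorm(50); y <- 3 - 2 * x + rnorm(50)
  fit <- ols_fit(design_matrix(data.frame(y = y, x = x), "y", "x"))
  expect_equal(unname(fit$beta["x"]), cov(x, y) / var(x), tolerance = 1e-10)
})

test_that("the 2SLS stage matches a brute-force IV oracle", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(15:30, 1)
    X <- cbind(1, rnorm(n), rnorm(n))
    H <- cbind(X, rnorm(n), rnorm(n))
    endo <- H[, 4] + rnorm(n)           # correlated with an instrument
    Z <- cbind(X, endo)
    y <- Z %*% c(1, 0.5, -0.5, 2) + rnorm(n)
    expect_equal(iv_fit(y, Z, H)$delta, iv_brute(y, Z, H), tolerance = 1e-8)
  }
})

test_that("LM diagnostics: degenerate weights give zero statistics", {
  d <- sim_design(20, seed = 2)
  w0 <- weights_matrix(rep(list(integer(0)), 20))
  lt <- lm_diagnostics(ols_fit(d), d, w0)
  expect_equal(lt$lm_lag$statistic, 0)
  expect_equal(lt$lm_error$statistic, 0)
  expect_equal(lt$recommendation, "ols")
})

test_that("LM recommendation detects a pure spatial-lag process", {
  w <- row_standardize(contiguity_weights(make_lattice(15, 15), "queen"))
  W <- as_spmatrix(w)
  A <- Matrix::solve(Matrix::Diagonal(225) - 0.4 * W)
  set.seed(61)
  recs <- character(40)
  for (r in 1:40) {
    x <- rnorm(225)
    y <- as.numeric(A %*% (1 + 2 * x + rnorm(225)))
    d <- design_matrix(data.frame(y = y, x = x), "y", "x")
    recs[r] <- lm_diagnostics(ols_fit(d), d, w)$recommendation
  }
  expect_gt(mean(recs == "lag"), 0.5)
  expect_lt(mean(recs == "error"), 0.1)
})

test_that("SARAR with empty weights reproduces OLS exactly", {
  d <- sim_design(50, seed = 19)
  w0 <- weights_matrix(rep(list(integer(0)), 50))
  f <- sarar_fit(d, w0, w0)
  ols <- ols_fit(d)
  expect_equal(f$beta, ols$beta, tolerance = 1e-8)
  expect_equal(f$lambda_lag, 0)
  expect_equal(f$rho_err, 0)
})

test_that("SARAR under a null spatial DGP tracks OLS within sampling error", {
  w <- row_standardize(contiguity_weights(make_lattice(10, 10), "queen"))
  set.seed(23)
  x <- rnorm(100)
  y <- 1 + 2 * x + rnorm(100)
  d <- design_matrix(data.frame(y = y, x = x), "y", "x")
  f <- sarar_fit(d, w)
  ols <- ols_fit(d)
  expect_lt(abs(f$lambda_lag), 0.25)
  expect_lt(abs(f$rho_err), 0.35)
  expect_lt(max(abs(f$beta - ols$beta)), 0.5)
  expect_true(all(f$se > 0))
})

test_that("SARAR recovers moderate lag and error parameters", {
  cfgs <- lapply(1:30, function(r)
    synthetic_config(rows = 12, cols = 12, lambda_lag = 0.4, rho_err = 0.3,
                     beta = c(x_smooth = 1, x_noise = 2), seed = 1000 + r))
  geo <- make_lattice(12, 12)
  w <- row_standardize(contiguity_weights(geo, "queen"))
  ests <- t(vapply(cfgs, function(cf) {
    g <- gen_outcomes(geo, w, w, cf)
    tab <- merge(g$covariates, g$outcomes, by = "unit_id")
    d <- design_matrix(tab, "y", c("x_smooth", "x_noise"))
    f <- sarar_fit(d, w)
    c(f$lambda_lag, f$rho_err, f$beta["x_smooth"], f$beta["x_noise"])
  }, numeric(4)))
  expect_lt(abs(mean(ests[, 1]) - 0.4), 0.08)
  expect_lt(abs(mean(ests[, 2]) - 0.3), 0.12)
  expect_lt(abs(mean(ests[, 3]) - 1), 0.1)
  expect_lt(abs(mean(ests[, 4]) - 2), 0.1)
})

test_that("coefficient comparison reproduces the worked z and handles rules", {
  fit_a <- list(beta = c(h_avg = -1.294), se = c(h_avg = 0.211))
  fit_b <- list(beta = c(h_avg = -0.421), se = c(h_avg = 0.155))
  cc <- compare_coefficients(fit_a, fit_b, "h_avg", variance_rule = "sum")
  expect_equal(cc$z, -0.873 / sqrt(0.211^2 + 0.155^2), tolerance = 1e-12)
  expect_equal(cc$z, -3.334, tolerance = 0.01)
  expect_lt(cc$p, 0.001)
  # identical fits: z = 0, p = 1
  cc0 <- compare_coefficients(fit_a, fit_a, "h_avg")
  expect_equal(cc0$z, 0)
  expect_equal(cc0$p, 1)
  # nested difference rule needs se_a > se_b
  expect_equal(
    compare_coefficients(fit_a, fit_b, "h_avg", "difference")$z,
    -0.873 / sqrt(0.211^2 - 0.155^2), tolerance = 1e-12)
  expect_error(compare_coefficients(fit_b, fit_a, "h_avg", "difference"),
               "se_a > se_b")
  expect_error(compare_coefficients(fit_a, fit_a, "h_avg", "difference"),
               "se_a > se_b")
  expect_error(compare_coefficients(fit_a, fit_b, "nope"), "nope")
})
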