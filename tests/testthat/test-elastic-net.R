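test_that("extreme penalty shrinks all coefficients to zero", {
  ds <- evCompounds()
  params <- fitPreprocessor(ds)
  Z <- transformDescriptors(params, ds)
  for (m in c("passive", "sonication")) {
    fit <- fitElasticNet(Z, ds[[m]], alpha = 0.5, lambda = 1e6, method = m)
    expect_equal(unname(fit$coefficients), rep(0, 7))
    expect_equal(fit$intercept, mean(ds[[m]]), tolerance = 1e-10)
  }
})

test_that("unpenalized fit matches the normal-equations oracle", {
  set.seed(42)
  n <- 10; p <- 3
  Z <- scale(matrix(rnorm(n * p), n, p), scale = FALSE)  # centered columns
  colnames(Z) <- paste0("x", 1:p)
  y <- drop(Z %*% c(2, -1, 0.5)) + rnorm(n, sd = 0.3) + 10
  # independent oracle: solve the normal equations of the augmented design
  X <- cbind(1, Z)
  beta_ols <- solve(crossprod(X), crossprod(X, y))
  fit <- fitElasticNet(Z, y, alpha = 0.5, lambda = 0)
  expect_equal(unname(fit$coefficients), unname(beta_ols[-1]),
               tolerance = 1e-6)
  expect_equal(fit$intercept, unname(beta_ols[1]), tolerance = 1e-6)
})

test_that("intercept equals the response mean for centered predictors", {
  ds <- evCompounds()
  params <- fitPreprocessor(ds)
  Z <- transformDescriptors(params, ds)
  for (m in evMethods()) {
    for (hp in list(c(0.1, 0.01), c(0.5, 1), c(0.9, 50))) {
      fit <- fitElasticNet(Z, ds[[m]], alpha = hp[1], lambda = hp[2])
      expect_equal(fit$intercept, mean(ds[[m]]), tolerance = 1e-8)
    }
  }
})

test_that("fitted penalty value is non-increasing in lambda", {
  ds <- evCompounds()
  params <- fitPreprocessor(ds)
  Z <- transformDescriptors(params, ds)
  y <- ds$passive
  for (alpha in c(0.1, 0.9)) {
    pen <- sapply(10^seq(-3, 2, length.out = 12), function(lam) {
      b <- fitElasticNet(Z, y, alpha, lam)$coefficients
      alpha * sum(abs(b)) + (1 - alpha) * sum(b^2)
    })
    expect_true(all(diff(pen) <= 1e-8))
  }
})

test_that("rejects degenerate inputs", {
  Z <- matrix(rnorm(20), 10, 2)
  expect_error(fitElasticNet(Z, rnorm(5), 0.5, 1), "length")
  Zbad <- Z; Zbad[1, 1] <- NA
  expect_error(fitElasticNet(Zbad, rnorm(10), 0.5, 1), "non-finite")
  expect_error(fitConfig(alpha_grid = numeric(0)), "non-empty")
  expect_error(fitConfig(lambda_grid = -1), ">= 0")
  expect_error(fitConfig(alpha_grid = 1.5), "alpha")
})

test_that("tuning a singleton grid returns that pair, deterministically", {
  train <- splitPredefined(evCompounds())$train
  cfg <- cfg_single(alpha = 0.3, lambda = 2)
  hp <- tuneHyperparameters(train, "passive", cfg)
  expect_equal(hp$alpha, 0.3)
  expect_equal(hp$lambda, 2)

  cfg2 <- cfg_small()
  hp1 <- tuneHyperparameters(train, "freeze_thaw", cfg2)
  hp2 <- tuneHyperparameters(train, "freeze_thaw", cfg2)
  expect_identical(hp1[c("alpha", "lambda")], hp2[c("alpha", "lambda")])
})

test_that("tuning ties break toward larger lambda then smaller alpha", {
  # constant response: every (alpha, lambda) gives the same LOO error,
  # so the tie rule alone decides
  df <- as.data.frame(splitPredefined(evCompounds())$train)
  df$passive <- 50
  cfg <- cfg_small()
  hp <- tuneHyperparameters(new_ev_dataset(df), "passive", cfg)
  expect_equal(hp$lambda, max(cfg$lambda_grid))
  expect_equal(hp$alpha, min(cfg$alpha_grid))
})

test_that("noiseless sparse linear data is recovered by the tuned model", {
  B <- matrix(0, 5, 7)
  B[1, c(1, 6)] <- c(12, -8)  # passive: logp up, psa down, all else zero
  spec <- generatorSpec(n_compounds = 40, coefficients = B,
                        intercepts = rep(50, 5), noise_sd = 0, seed = 11L)
  ds <- generateCompounds(spec)
  hp <- tuneHyperparameters(ds, "passive", cfg_small())
  params <- fitPreprocessor(ds)
  fit <- fitElasticNet(transformDescriptors(params, ds), ds$passive,
                       hp$alpha, hp$lambda)
  expect_equal(unname(fit$coefficients[c("logp", "psa")]), c(12, -8),
               tolerance = 0.1)
  expect_true(all(abs(fit$coefficients[c(2:5, 7)]) < 0.5))
})

test_that("coefficients are recovered within 10% on strong-signal data", {
  B <- rbind(c(8, -6, 5, 0, 0, -7, 6),
             c(-5, 7, 0, 6, -8, 0, 5),
             c(6, 0, -7, -5, 8, 5, 0),
             c(0, 5, 6, 8, 0, -6, -7),
             c(-7, -5, 0, 0, 6, 8, 5))
  spec <- generatorSpec(n_compounds = 200, coefficients = B,
                        intercepts = rep(50, 5), noise_sd = 1, seed = 3L)
  ds <- generateCompounds(spec)
  params <- fitPreprocessor(ds)
  Z <- transformDescriptors(params, ds)
  for (k in seq_along(evMethods())) {
    fit <- fitElasticNet(Z, ds[[evMethods()[k]]], alpha = 0.5, lambda = 0.01)
    nz <- B[k, ] != 0
    expect_lt(max(abs(fit$coefficients[nz] - B[k, nz]) / abs(B[k, nz])), 0.1)
  }
})

test_that("identical response columns give identical models", {
  df <- as.data.frame(splitPredefined(evCompounds())$train)
  df$electroporation <- df$sonication
  ms <- fitAllMethods(new_ev_dataset(df), cfg_small())
  expect_equal(ms$models$electroporation[c("intercept", "coefficients",
                                           "alpha", "lambda")],
               ms$models$sonication[c("intercept", "coefficients",
                                      "alpha", "lambda")])
})

test_that("equation export carries full precision and readable form", {
  ms <- fitAllMethods(splitPredefined(evCompounds())$train, cfg_small())
  eq <- exportEquations(ms)
  expect_equal(eq$method, evMethods())
  expect_equal(names(eq), c("method", "intercept", evDescriptors(),
                            "alpha", "lambda"))
  expect_equal(eq$intercept[1], ms$models$passive$intercept)

  shrunk <- fitElasticNet(diag(3), c(1, 2, 3), 0.5, 1e6)
  expect_match(formatEquation(shrunk), "^LE_y = 2\\.00$")
})
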