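test_that("regression metrics match independently coded formulas", {
  set.seed(9)
  y <- rnorm(20, 30, 12)
  p <- y + rnorm(20, 0, 5)
  m <- regressionMetrics(y, p)
  # independent re-implementation, written out long-hand
  abs_err <- abs(y - p)
  expect_equal(m$mae, sum(abs_err) / 20, tolerance = 1e-12)
  expect_equal(m$rmse, sqrt(sum((y - p)^2) / 20), tolerance = 1e-12)
  expect_equal(m$r2, 1 - sum((y - p)^2) / sum((y - sum(y) / 20)^2),
               tolerance = 1e-12)
  expect_gte(m$rmse, m$mae)

  expect_equal(regressionMetrics(y, y)[c("mae", "rmse", "r2")],
               list(mae = 0, rmse = 0, r2 = 1))
  null_model <- regressionMetrics(y, rep(mean(y), 20))
  expect_equal(null_model$r2, 0, tolerance = 1e-12)

  expect_warning(zv <- regressionMetrics(rep(5, 4), c(4, 5, 6, 5)),
                 "zero variance")
  expect_equal(zv$r2, 0)
  expect_true(zv$zero_variance)

  expect_error(regressionMetrics(1:3, 1:4), "equal")
})

test_that("noiseless well-separated data validates perfectly", {
  ds <- generateCompounds(separated_spec(n = 14))
  rep <- loocvValidate(ds, cfg_small())
  expect_equal(rep$decision_accuracy, 1)
  expect_equal(rep$n_total, 14)
  # the methods with signal are predicted almost exactly
  expect_gt(rep$per_method$passive$r2, 0.99)
  expect_gt(rep$per_method$saponin$r2, 0.99)
})

test_that("LOOCV decision accuracy is invariant to record order", {
  ds <- generateCompounds(separated_spec(n = 10, noise_sd = 8))
  cfg <- cfg_single(alpha = 0.5, lambda = 0.5)
  a <- loocvValidate(ds, cfg)
  perm <- new_ev_dataset(as.data.frame(ds)[c(7, 2, 9, 4, 10, 1, 3, 8, 5, 6), ])
  b <- loocvValidate(perm, cfg)
  expect_equal(b$decision_accuracy, a$decision_accuracy)
  expect_equal(sort(b$per_compound$name[b$per_compound$correct]),
               sort(a$per_compound$name[a$per_compound$correct]))
})

test_that("external validation rejects overlapping sets and matches resubstitution", {
  sp <- splitPredefined(evCompounds())
  expect_error(externalValidate(sp$train, sp$train, cfg_small()), "overlap")

  # external set = copy of training compounds (renamed to pass the overlap
  # guard): accuracy equals training resubstitution accuracy
  cfg <- cfg_single(alpha = 0.5, lambda = 1)
  copy <- as.data.frame(sp$train)
  copy$name <- paste0(copy$name, "_copy")
  rep <- externalValidate(sp$train, new_ev_dataset(copy), cfg)
  ms <- fitAllMethods(sp$train, cfg)
  resub <- mean(predictedOptimal(ms, sp$train) == observedOptimal(sp$train))
  expect_equal(rep$decision_accuracy, resub)
})

test_that("a single random split agrees with externalValidate on that split", {
  ds <- evCompounds()
  cfg <- cfg_small()
  seed <- 13L
  rep1 <- repeatedRandomValidate(ds, n_reps = 1, test_size = 4,
                                 seed = seed, cfg = cfg)
  # reproduce the draw with the same generator
  idx <- local({ set.seed(seed); sample.int(21, 4) })
  expect_setequal(rep1$test_sets[[1]], ds$name[idx])
  df <- as.data.frame(ds)
  rep2 <- externalValidate(new_ev_dataset(df[-idx, ]),
                           new_ev_dataset(df[idx, ]), cfg)
  expect_equal(rep1$rep_accuracy, rep2$decision_accuracy)
  expect_equal(rep1$per_compound$predicted_optimal,
               rep2$per_compound$predicted_optimal)
})

test_that("repeated random accuracies live on the attainable lattice", {
  ds <- generateCompounds(separated_spec(n = 12, noise_sd = 10))
  cfg <- cfg_single(alpha = 0.5, lambda = 0.5)
  rep <- repeatedRandomValidate(ds, n_reps = 6, test_size = 4,
                                seed = 2L, cfg = cfg)
  expect_true(all(rep$rep_accuracy %in% c(0, 0.25, 0.5, 0.75, 1)))
  expect_equal(rep$mean_accuracy, mean(rep$rep_accuracy))
  expect_equal(rep$sd_accuracy, stats::sd(rep$rep_accuracy))
  expect_equal(rep$decision_accuracy, rep$mean_accuracy)
  expect_error(repeatedRandomValidate(ds, n_reps = 0, seed = 1), "n_reps")
  expect_error(repeatedRandomValidate(ds, test_size = 12, seed = 1),
               "test_size")
})

test_that("noiseless dominant-method data gives perfect stability", {
  B <- matrix(0, 5, 7); B[1, 1] <- 5
  spec <- generatorSpec(n_compounds = 10, coefficients = B,
                        intercepts = c(80, 10, 10, 10, 10),
                        noise_sd = 0, seed = 4L)
  rep <- repeatedRandomValidate(generateCompounds(spec), n_reps = 3,
                                test_size = 3, seed = 4L,
                                cfg = cfg_single(lambda = 0.5))
  expect_equal(rep$mean_accuracy, 1)
  expect_equal(rep$sd_accuracy, 0)
})

test_that("reports serialize with decision and metric tables intact", {
  ds <- generateCompounds(separated_spec(n = 10))
  rep <- loocvValidate(ds, cfg_single(lambda = 0.1))
  lst <- reportToList(rep)
  expect_equal(lst$decision_accuracy, rep$decision_accuracy)
  expect_named(lst$per_method, evMethods())
  tab <- metricsTable(rep)
  expect_equal(dim(tab), c(5L, 4L))
  dt <- decisionTable(rep)
  expect_equal(nrow(dt), 10)
  expect_true(all(dt$observed_optimal %in% methodLabel(evMethods())))
})
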