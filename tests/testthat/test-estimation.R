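test_that("rmse follows its definition and rejects bad input", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(1, 3), c(2, 2)), 1)
  expect_equal(rmse(c(0, 0, 0), c(3, 0, 0)), sqrt(3))
  expect_error(rmse(1:3, 1:2), "equal nonzero length")
  expect_error(rmse(numeric(0), numeric(0)), "equal nonzero length")
})

test_that("noiseless self-simulated data is recovered within 1% per parameter", {
  cases <- list(
    list(id = "gompertz", truth = c(A = 1, muMax = 0.2, lambda = 5),
         grid = c(0, 48, 0.5)),
    list(id = "logistic", truth = c(A = 1, muMax = 0.25, lambda = 4),
         grid = c(0, 48, 0.5)),
    list(id = "exp_decay", truth = c(y0 = 2, k = 0.3, offset = 0.2),
         grid = c(0, 20, 0.2))
  )
  for (cs in cases) {
    dat <- noiselessSeries(cs$id, cs$truth, cs$grid[1], cs$grid[2], cs$grid[3])
    fit <- fitModel(cs$id, dat, rangesAroundTruth(cs$truth),
                    fitOptions(nStarts = 10, seed = 7))
    expect_true(isConverged(fit), label = cs$id)
    expect_lt(maxRelErr(estimates(fit), cs$truth), 0.01)
    # reported RMSE always equals an independent recomputation
    expect_identical(fitRMSE(fit),
                     rmse(dat$value, fittedCurve(fit)$value))
  }
})

test_that("ODE-in-the-loop fitting recovers spheroid parameters within 5%", {
  truth <- c(alpha = 0.2, delta = 0.05, lambdaDepth = 1, r0 = 0.5)
  dat <- noiselessSeries("lcf", truth, 0, 40, 1)
  fit <- fitModel("lcf", dat, rangesAroundTruth(truth, init = "r0"),
                  fitOptions(nStarts = 20, seed = 11))
  expect_true(isConverged(fit))
  expect_lt(maxRelErr(estimates(fit), truth), 0.05)
})

test_that("first-order polynomial fit agrees with closed-form OLS to 1e-10", {
  set.seed(42)
  tm <- seq(0, 10, 0.5)
  y <- 1.2 + 0.7 * tm + rnorm(length(tm), 0, 0.3)
  dat <- data.frame(time = tm, value = y)
  fit <- fitModel("poly1", dat, options = fitOptions(nStarts = 5, seed = 1))
  ols <- coef(lm(y ~ tm))
  expect_equal(estimates(fit)[["c0"]], unname(ols[1]), tolerance = 1e-10)
  expect_equal(estimates(fit)[["c1"]], unname(ols[2]), tolerance = 1e-10)
  # two points: exact interpolation, rmse 0
  f2 <- fitModel("poly1", data.frame(time = c(0, 2), value = c(1, 5)),
                 options = fitOptions(nStarts = 3, seed = 1))
  expect_equal(estimates(f2)[["c0"]], 1, tolerance = 1e-8)
  expect_equal(estimates(f2)[["c1"]], 2, tolerance = 1e-8)
  expect_lt(fitRMSE(f2), 1e-9)
})

test_that("estimates respect box constraints even when truth sits outside", {
  dat <- noiselessSeries("gompertz", c(A = 1, muMax = 0.2, lambda = 5),
                         0, 48, 0.5)
  sp <- rbind(parameterSpec("A", 0.2, 0.8),   # truth A=1 excluded
              parameterSpec("muMax", 0.02, 2),
              parameterSpec("lambda", 0.5, 50))
  fit <- fitModel("gompertz", dat, sp, fitOptions(nStarts = 10, seed = 3))
  est <- estimates(fit)
  expect_true(all(est >= sp$lower - 1e-12 & est <= sp$upper + 1e-12))
  expect_equal(est[["A"]], 0.8, tolerance = 1e-6)  # pressed onto the boundary
})

test_that("fitting is deterministic given identical inputs and seed", {
  dat <- noiselessSeries("gompertz", c(A = 1, muMax = 0.2, lambda = 5),
                         0, 48, 1)
  sp <- rangesAroundTruth(c(A = 1, muMax = 0.2, lambda = 5))
  f1 <- fitModel("gompertz", dat, sp, fitOptions(nStarts = 8, seed = 5))
  f2 <- fitModel("gompertz", dat, sp, fitOptions(nStarts = 8, seed = 5))
  expect_identical(estimates(f1), estimates(f2))
  expect_identical(fitRMSE(f1), fitRMSE(f2))
})

test_that("degenerate and invalid inputs are rejected at entry", {
  expect_error(fitModel("gompertz",
                        data.frame(time = 0:10, value = rep(2, 11))),
               "degenerate")
  expect_error(fitModel("gompertz",
                        data.frame(time = 0:1, value = c(0.1, NA))),
               "non-finite")
  expect_error(fitModel("gompertz",
                        data.frame(time = 0:1, value = c(0.1, 0.2))),
               "cannot identify")
  expect_error(fitModel("gompertz",
                        data.frame(time = 0:5, value = c(-1, 1:5)),
                        options = fitOptions(scale = "log")),
               "positive")
})

test_that("pinned parameters are held fixed and must lie in range", {
  truth <- c(A = 1, muMax = 0.2, lambda = 5)
  dat <- noiselessSeries("gompertz", truth, 0, 48, 0.5)
  sp <- rangesAroundTruth(truth)
  fit <- fitModel("gompertz", dat, sp,
                  fitOptions(nStarts = 5, seed = 1, pin = c(A = 1)))
  expect_identical(estimates(fit)[["A"]], 1)
  expect_lt(maxRelErr(estimates(fit), truth), 0.01)
  expect_error(fitModel("gompertz", dat, sp,
                        fitOptions(pin = c(A = 99))), "outside search range")
  expect_error(fitModel("gompertz", dat, sp,
                        fitOptions(pin = c(zz = 1))), "not in spec")
})

test_that("log-scale fitting minimizes log-space residuals but reports raw RMSE", {
  truth <- c(A = 1, muMax = 0.2, lambda = 5)
  dat <- noiselessSeries("gompertz", truth, 0, 48, 0.5)
  fit <- fitModel("gompertz", dat, rangesAroundTruth(truth),
                  fitOptions(nStarts = 8, seed = 2, scale = "log"))
  expect_lt(maxRelErr(estimates(fit), truth), 0.01)
  expect_identical(fitRMSE(fit), rmse(dat$value, fittedCurve(fit)$value))
})

test_that("pooled fitting: single dataset identical to fitModel, pooled optimum between replicate optima", {
  truth <- c(A = 1, muMax = 0.2, lambda = 5)
  sp <- rangesAroundTruth(truth)
  dat <- noiselessSeries("gompertz", truth, 0, 48, 1)
  opts <- fitOptions(nStarts = 6, seed = 9)
  expect_identical(estimates(fitAggregate("gompertz", list(dat), sp, opts)),
                   estimates(fitModel("gompertz", dat, sp, opts)))

  # replicates generated at A = 1.0 and A = 1.2, other parameters shared
  d1 <- noiselessSeries("gompertz", c(A = 1.0, muMax = 0.2, lambda = 5), 0, 48, 1)
  d2 <- noiselessSeries("gompertz", c(A = 1.2, muMax = 0.2, lambda = 5), 0, 48, 1)
  pooled <- fitAggregate("gompertz", list(d1, d2), sp,
                         fitOptions(nStarts = 10, seed = 4))
  Ahat <- estimates(pooled)[["A"]]
  expect_gt(Ahat, 1.0)
  expect_lt(Ahat, 1.2)

  # brute-force oracle: grid search over A with muMax, lambda at truth
  grid <- seq(1.0, 1.2, by = 0.001)
  cost <- vapply(grid, function(A) {
    pr1 <- gompertzValue(d1$time, A, 0.2, 5)
    pr2 <- gompertzValue(d2$time, A, 0.2, 5)
    sum((d1$value - pr1)^2) + sum((d2$value - pr2)^2)
  }, 0)
  expect_equal(Ahat, grid[which.min(cost)], tolerance = 0.002)
})

test_that("three noiseless replicates refit to the shared truth within 1%", {
  truth <- c(A = 1, muMax = 0.2, lambda = 5)
  dat <- noiselessSeries("gompertz", truth, 0, 48, 0.5)
  pooled <- fitAggregate("gompertz", list(dat, dat, dat),
                         rangesAroundTruth(truth),
                         fitOptions(nStarts = 8, seed = 2))
  expect_lt(maxRelErr(estimates(pooled), truth), 0.01)
  expect_error(fitAggregate("gompertz", list()), "nonempty list")
})

test_that("manual log-linear regression matches closed-form OLS", {
  tm <- seq(0, 10, 0.5)
  exact <- data.frame(time = tm, value = 0.05 * exp(0.3 * tm))
  lf <- manualLogRegression(exact, c(0, 10))
  expect_equal(lf@slope, 0.3, tolerance = 1e-12)
  expect_equal(lf@intercept, log(0.05), tolerance = 1e-12)
  expect_equal(lf@rSquared, 1, tolerance = 1e-12)

  # constant data: slope 0
  cf <- manualLogRegression(data.frame(time = 0:5, value = rep(2, 6)), c(0, 5))
  expect_equal(cf@slope, 0, tolerance = 1e-12)

  # noisy exponential against the hand-computed OLS formulas
  set.seed(17)
  y <- 0.05 * exp(0.3 * tm) * exp(rnorm(length(tm), 0, 0.01))
  nf <- manualLogRegression(data.frame(time = tm, value = y), c(0, 10))
  ly <- log(y)
  slope <- sum((tm - mean(tm)) * (ly - mean(ly))) / sum((tm - mean(tm))^2)
  expect_equal(nf@slope, slope, tolerance = 1e-12)
  expect_equal(nf@intercept, mean(ly) - slope * mean(tm), tolerance = 1e-12)

  # windowing and error paths
  expect_error(manualLogRegression(exact, c(0, 0.1)), "at least 2 points")
  neg <- data.frame(time = 0:3, value = c(1, -1, 2, 3))
  expect_error(manualLogRegression(neg, c(0, 3)), "t = 1")
})

test_that("model comparison ranks the generating model first and keeps failures", {
  truth <- c(A = 1, muMax = 0.2, lambda = 5)
  dat <- noiselessSeries("gompertz", truth, 0, 48, 1)
  opts <- fitOptions(nStarts = 6, seed = 3)
  tbl <- compareModels(dat, c("poly1", "gompertz"), opts)
  expect_identical(tbl$modelId[1], "gompertz")
  expect_true(all(diff(tbl$rmse[tbl$converged]) >= 0))

  # single candidate equals the plain fit
  one <- compareModels(dat, "gompertz", opts)
  expect_identical(nrow(one), 1L)
  expect_identical(one$rmse[1], fitRMSE(fitModel("gompertz", dat,
                                                 options = opts)))

  # order invariance under fixed per-fit seed
  fwd <- compareModels(dat, c("gompertz", "logistic", "poly1"), opts)
  rev <- compareModels(dat, c("poly1", "logistic", "gompertz"), opts)
  expect_identical(fwd[c("modelId", "rmse", "converged")],
                   rev[c("modelId", "rmse", "converged")])

  # a failing candidate is recorded, not fatal
  tbl2 <- compareModels(dat, c("gompertz", "lcf"), opts)
  expect_identical(nrow(tbl2), 2L)
})

test_that("fitted RMSE concentrates near the injected noise level", {
  # additive sigma = 0.02, n = 200: fitted RMSE within 20% over seeds
  truth <- c(A = 1, muMax = 0.2, lambda = 5)
  sp <- rangesAroundTruth(truth)
  rmses <- vapply(1:5, function(sd0) {
    gen <- generateCurve(generationSpec("gompertz", truth, 0, 49.75, 0.25,
                                        noise = "additive_gaussian",
                                        sigma = 0.02, seed = sd0))
    fitRMSE(fitModel("gompertz", gen$measurements[[1]], sp,
                     fitOptions(nStarts = 4, seed = 1)))
  }, 0)
  expect_lt(abs(median(rmses) - 0.02) / 0.02, 0.2)
})
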