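test_that("measurement CSV import parses layout, header and delimiters", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0,0.05", "1,0.08", "2,0.15"), p)
  m <- importMeasurementCSV(p)
  expect_equal(m@time, c(0, 1, 2))
  expect_equal(m@value, c(0.05, 0.08, 0.15))

  # header auto-detection yields the identical series
  writeLines(c("time,od", "0,0.05", "1,0.08", "2,0.15"), p)
  m2 <- importMeasurementCSV(p)
  expect_equal(m2@time, m@time)
  expect_equal(m2@value, m@value)

  # semicolon and tab dialects
  writeLines(c("0;0.05", "1;0.08"), p)
  expect_equal(importMeasurementCSV(p)@value, c(0.05, 0.08))
  writeLines(c("0\t0.05", "1\t0.08"), p)
  expect_equal(importMeasurementCSV(p)@time, c(0, 1))

  # third numeric column -> extra; trailing text -> annotation
  writeLines(c("time,od,temp,note", "0,0.05,37,start", "1,0.08,37.2,"), p)
  m3 <- importMeasurementCSV(p)
  expect_equal(m3@extra, c(37, 37.2))
  expect_identical(m3@annotation, c("start", ""))
})

test_that("rows out of time order are sorted with pairing preserved", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("2,0.15", "0,0.05", "1,0.08"), p)
  m <- importMeasurementCSV(p)
  expect_equal(m@time, c(0, 1, 2))
  expect_equal(m@value, c(0.05, 0.08, 0.15))
})

test_that("import rejects bad rows with line numbers and duplicate times", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0,0.05", "1,oops", "2,0.15"), p)
  expect_error(importMeasurementCSV(p), "line 2")
  writeLines(c("0,0.05", "0,0.08"), p)
  expect_error(importMeasurementCSV(p), "duplicate time")
  writeLines("justonecolumn", p)
  expect_error(importMeasurementCSV(p), "delimiter")
})

test_that("import/export round-trip reproduces numeric content exactly", {
  m <- Measurement("rt", time = c(0, 1/3, exp(1), pi),
                   value = c(0.1, 2/7, 1e-17, 123456.789012345),
                   extra = c(1, 2, 3, 4) / 3,
                   annotation = c("a", "", "c", "d"))
  p <- withr::local_tempfile(fileext = ".csv")
  exportMeasurementCSV(m, p)
  back <- importMeasurementCSV(p, measurementId = "rt")
  expect_identical(back@time, m@time)
  expect_identical(back@value, m@value)
  expect_identical(back@extra, m@extra)
  expect_identical(back@annotation, m@annotation)
})

test_that("extra dimension and annotations are inert for fitting", {
  truth <- c(A = 1, muMax = 0.2, lambda = 5)
  tm <- seq(0, 48, 1)
  vals <- gompertzValue(tm, 1, 0.2, 5)
  bare <- Measurement("bare", tm, vals)
  rich <- Measurement("rich", tm, vals, extra = seq_along(tm),
                      annotation = rep("x", length(tm)))
  opts <- fitOptions(nStarts = 5, seed = 2)
  sp <- rangesAroundTruth(truth)
  expect_identical(estimates(fitModel("gompertz", bare, sp, opts)),
                   estimates(fitModel("gompertz", rich, sp, opts)))
})

test_that("results CSV export writes declared columns and round-trips values", {
  truth <- c(A = 1, muMax = 0.2, lambda = 5)
  tm <- seq(0, 48, 1)
  m1 <- Measurement("m1", tm, gompertzValue(tm, 1, 0.2, 5))
  m2 <- Measurement("m2", tm, gompertzValue(tm, 1.1, 0.25, 4))
  e <- Experiment("e1", measurements = list(m1, m2))
  opts <- fitOptions(nStarts = 5, seed = 2)
  sp <- rangesAroundTruth(truth)
  f1 <- fitModel("gompertz", m1, sp, opts)
  f2 <- fitModel("gompertz", m2, sp, opts)
  e <- attachFit(e, "m1", f1)
  e <- attachFit(e, "m2", f2)

  p <- withr::local_tempfile(fileext = ".csv")
  n <- exportResultsCSV(e, "gompertz", p)
  expect_identical(n, 2L)
  got <- read.csv(p)
  expect_identical(names(got),
                   c("measurement", "A", "muMax", "lambda", "rmse",
                     "converged", "n_points"))
  expect_identical(got$A, unname(c(estimates(f1)[["A"]], estimates(f2)[["A"]])))
  expect_identical(as.numeric(got$rmse), c(fitRMSE(f1), fitRMSE(f2)))

  # no fits for a model: header-only file, 0 rows
  p2 <- withr::local_tempfile(fileext = ".csv")
  expect_identical(exportResultsCSV(e, "logistic", p2), 0L)
  expect_identical(length(readLines(p2)), 1L)
})

test_that("repository save/load round-trip is lossless", {
  root <- withr::local_tempdir()
  # empty repository
  saveRepository(GrowthRepository(), file.path(root, "empty"))
  expect_identical(length(projects(loadRepository(file.path(root, "empty")))),
                   0L)

  tm <- seq(0, 24, 1)
  m1 <- Measurement("m1", tm, gompertzValue(tm, 1, 0.2, 5),
                    annotation = rep("od600", length(tm)))
  m2 <- Measurement("m2", tm, gompertzValue(tm, 1.2, 0.3, 4),
                    extra = tm * 2)
  m3 <- Measurement("m3", tm, logisticValue(tm, 1, 0.25, 4))
  e1 <- Experiment("e1", name = "glucose", measurements = list(m1, m2))
  e2 <- Experiment("e2", name = "lactose", measurements = list(m3))
  fit <- fitModel("gompertz", m1,
                  rangesAroundTruth(c(A = 1, muMax = 0.2, lambda = 5)),
                  fitOptions(nStarts = 4, seed = 1))
  e1 <- attachFit(e1, "m1", fit)
  repo <- GrowthRepository(list(Project("p1", name = "sugars",
                                        description = "carbon sources",
                                        experiments = list(e1, e2))))
  saveRepository(repo, file.path(root, "full"))
  back <- loadRepository(file.path(root, "full"))

  expect_identical(length(projects(back)), 1L)
  pb <- projects(back)[[1]]
  expect_identical(pb@name, "sugars")
  expect_identical(pb@description, "carbon sources")
  eb <- experiments(pb)[[1]]
  expect_identical(vapply(measurements(eb), function(m) m@measurementId, ""),
                   c("m1", "m2"))
  mb <- measurements(eb)[[1]]
  expect_identical(mb@time, m1@time)
  expect_identical(mb@value, m1@value)
  expect_identical(mb@annotation, m1@annotation)
  expect_identical(measurements(eb)[[2]]@extra, m2@extra)
  fb <- eb@fits[[1]]
  expect_identical(fb$modelId, "gompertz")
  expect_identical(estimates(fb$fit), estimates(fit))
  expect_identical(fitRMSE(fb$fit), fitRMSE(fit))
  expect_identical(fb$fit@fittedValues, fit@fittedValues)

  # deleting a measurement file is detected by name
  unlink(file.path(root, "full", "projects", "p1", "experiments", "e1",
                   "measurements", "m2.csv"))
  expect_error(loadRepository(file.path(root, "full")), "m2\\.csv")
})

test_that("hierarchy constructors enforce identifier uniqueness", {
  m <- Measurement("m1", 0:2, c(1, 2, 3))
  expect_error(Experiment("e", measurements = list(m, m)), "unique")
  expect_error(Measurement("bad id!", 0:2, c(1, 2, 3)), "may only contain")
  expect_error(Measurement("m", c(0, 1, 1), c(1, 2, 3)), "duplicate")
  e <- Experiment("e", measurements = list(m))
  expect_error(attachFit(e, "nope",
                         new("GrowthFit", modelId = "poly1",
                             estimates = c(c0 = 0, c1 = 1), rmse = 0,
                             nPoints = 3L, converged = TRUE,
                             nStartsUsed = 1L, fittedTimes = 0:2,
                             fittedValues = c(1, 2, 3))),
               "unknown measurement")
})
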