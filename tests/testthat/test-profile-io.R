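test_that("long-format CSV writes and reads back to formatting precision", {
  runs <- list(singleSpeciesRun("HSA"), singleSpeciesRun("LYZ"))
  path <- file.path(withr::local_tempdir(), "runs.csv")
  writeRuns(runs, path)
  back <- readRuns(path)
  expect_length(back, 2L)
  expect_equal(unname(sort(vapply(back, sampleId, ""))), c("HSA", "LYZ"))
  orig <- runs[[order(vapply(runs, sampleId, ""))[1]]]
  expect_equal(temperatures(back[[1]]), temperatures(orig), tolerance = 1e-5)
  expect_equal(f330(back[[1]]), f330(orig), tolerance = 1e-5)
  expect_equal(f350(back[[1]]), f350(orig), tolerance = 1e-5)
})

test_that("malformed scan files are rejected with the offending sample named", {
  dir <- withr::local_tempdir()
  bad <- data.frame(sample_id = "S1", temperature = c(40, 39, 41, 42),
                    f330 = 1:4, f350 = 1:4)
  bad <- bad[rep(1:4, 5), ]; bad$temperature <- c(seq(44, 41, -1), 41:56)
  path <- file.path(dir, "bad.csv")
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(readRuns(path), "S1.*increasing")

  neg <- data.frame(sample_id = "S2", temperature = seq(35, 54),
                    f330 = c(-1, rep(1, 19)), f350 = rep(1, 20))
  utils::write.csv(neg, path, row.names = FALSE)
  expect_error(readRuns(path), "S2")

  utils::write.csv(data.frame(sample_id = "S3", temp = 1:20, f330 = 1,
                              f350 = 1), path, row.names = FALSE)
  expect_error(readRuns(path), "missing required column")
})

test_that("wide-format files read one run per channel pair", {
  dir <- withr::local_tempdir()
  tt <- seq(35, 55, by = 1)
  wide <- data.frame(temperature = tt,
                     a_f330 = 100 + tt, a_f350 = 90 + tt,
                     b_f330 = 200 + tt, b_f350 = 150 + tt)
  path <- file.path(dir, "wide.csv")
  utils::write.csv(wide, path, row.names = FALSE)
  runs <- readRuns(path, dialect = "wide")
  expect_named(runs, c("a", "b"))
  expect_equal(f330(runs$b), 200 + tt)
})

test_that("resampling reproduces on-grid data, affine channels and a sine oracle", {
  run <- singleSpeciesRun("HSA")
  same <- resampleRun(run, TemperatureGrid())
  expect_equal(f330(same), f330(run), tolerance = 1e-12)

  tt <- seq(35, 95, by = 0.5)
  aff <- NanoDSFRun("aff", tt, 100 + 2 * tt, 300 - 1.5 * tt)
  res <- resampleRun(aff, TemperatureGrid())
  g <- gridTemps(TemperatureGrid())
  expect_equal(f330(res), 100 + 2 * g, tolerance = 1e-10)
  expect_equal(f350(res), 300 - 1.5 * g, tolerance = 1e-10)

  sine <- NanoDSFRun("sine", tt, 100 + 10 * sin(tt / 5), 100 + 10 * cos(tt / 5))
  resS <- resampleRun(sine, TemperatureGrid())
  expect_lt(max(abs(f330(resS) - (100 + 10 * sin(g / 5)))), 1e-4)

  expect_error(resampleRun(aff, TemperatureGrid(30, 95)), "extrapolation")
})

test_that("six-curve construction honours constants, slopes and a logistic apex", {
  tt <- gridTemps(TemperatureGrid())
  flat <- NanoDSFRun("flat", tt, rep(100, length(tt)), rep(80, length(tt)))
  sc <- sixCurves(flat)
  expect_lt(max(abs(sc@dF330)), 1e-9)
  expect_lt(max(abs(sc@dF350)), 1e-9)
  expect_lt(max(abs(sc@dRatio)), 1e-9)
  expect_equal(ratioCurve(sc), rep(0.8, length(tt)), tolerance = 1e-12)

  aff <- NanoDSFRun("aff", tt, 100 + 2 * tt, 300 + 0.5 * tt)
  scA <- sixCurves(aff)
  inner <- (scA@edgePoints + 1):(length(tt) - scA@edgePoints)
  expect_equal(scA@dF330[inner], rep(2, length(inner)), tolerance = 1e-8)
  expect_equal(scA@dF350[inner], rep(0.5, length(inner)), tolerance = 1e-8)

  # ratio that is a logistic step centred at 70: derivative apex at 70
  f330v <- rep(1000, length(tt))
  ratio <- 0.8 + 0.2 * stats::plogis((tt - 70) / 1.2)
  scL <- sixCurves(NanoDSFRun("lgs", tt, f330v, ratio * f330v))
  apex <- tt[which.max(dRatioCurve(scL))]
  expect_lte(abs(apex - 70), 0.05)
})

test_that("the derivative operator is linear and six-curves is idempotent", {
  tt <- gridTemps(TemperatureGrid())
  x <- 100 + 10 * sin(tt / 4)
  y <- 200 + 5 * cos(tt / 7)
  d <- function(v) sixCurves(NanoDSFRun("t", tt, v, v))@dF330
  expect_equal(d(3 * x + 2 * y), 3 * d(x) + 2 * d(y), tolerance = 1e-9)

  run <- singleSpeciesRun("LCN1")
  sc1 <- sixCurves(run)
  rerun <- NanoDSFRun("LCN1", sc1@temperatures, sc1@f330, sc1@f350)
  sc2 <- sixCurves(rerun)
  expect_equal(sc2@dRatio, sc1@dRatio, tolerance = 1e-12)
  expect_equal(ratioCurve(sc2), ratioCurve(sc1), tolerance = 1e-12)
})

test_that("too-small smoothing windows are a configuration error", {
  expect_error(sixCurves(singleSpeciesRun("HSA"), window = 0.2),
               "at least 3 grid steps")
})

test_that("run validity enforces scan invariants", {
  expect_error(NanoDSFRun("x", 1:10, rep(1, 10), rep(1, 10)), "16")
  expect_error(NanoDSFRun("x", c(1:15, 15), rep(1, 16), rep(1, 16)),
               "strictly increasing")
  expect_error(NanoDSFRun("x", 1:16, rep(0, 16), rep(1, 16)), "> 0")
})
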