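test_that("survey simulation is deterministic and respects the depth limit", {
  a <- smallSurvey()
  b <- simulateSurvey(smallScene(), smallEnv(), defaultTrueModel(),
                      surveyDesign(years = 2010:2013), seed = 13)
  expect_identical(a, b)
  expect_true(all(a$Min_Depth <= 3 & a$Min_Depth > 0))
  expect_true(all(a$effort > 0))
  expect_equal(a$nCaught,
               lengths(regmatches(a$lengthsSTL,
                                  gregexpr("[0-9.]+", a$lengthsSTL))))
})

test_that("catch mean is proportional to effort (offset linearity)", {
  # flat density, half the sets on short nets: effort ratio is exactly 2
  flat <- flatTrueModel(intercept = -9)
  des <- surveyDesign(years = 2010:2019, probShortNet = 0.5)
  sc <- smallScene()
  env <- generateEnvironment(sc, seq(as.Date("2010-01-01"),
                                     as.Date("2019-12-31"), by = "day"),
                             seed = 21)
  sv <- simulateSurvey(sc, env, flat, des, seed = 22)
  long <- sv$nCaught[sv$netLengthM == 61]
  short <- sv$nCaught[sv$netLengthM == 30.5]
  ratio <- mean(long) / mean(short)
  # delta-method SE of the ratio of means
  se <- ratio * sqrt(var(long) / (length(long) * mean(long)^2) +
                       var(short) / (length(short) * mean(short)^2))
  expect_lt(abs(ratio - 2), 3 * se)
})

test_that("near-gamma power with large dispersion drives zeros above one half", {
  flat <- flatTrueModel(p = 1.9, phi = 15)
  sv <- simulateSurvey(smallScene(), smallEnv(), flat,
                       surveyDesign(years = 2010:2011), seed = 23)
  mu <- sv$effort * exp(-11.4)
  p0 <- mean(tweedieZeroProb(mu, 1.9, 15))
  emp <- mean(sv$nCaught == 0)
  expect_gt(emp, 0.5)
  # the closed-form zero mass is a floor (integer rounding only adds zeros)
  expect_gt(emp, p0 - 3 * sqrt(p0 * (1 - p0) / nrow(sv)))
})

test_that("default calibration yields sparse catches at study scale", {
  sc <- generateScene(estuaryConfig(), seed = 1)
  env <- generateEnvironment(sc, seq(as.Date("2010-01-01"),
                                     as.Date("2022-12-31"), by = "day"),
                             seed = 2)
  sv <- simulateSurvey(sc, env, defaultTrueModel(), surveyDesign(), seed = 3)
  expect_gt(nrow(sv), 2300)        # of the order of 2543 sets
  expect_lt(nrow(sv), 2700)
  total <- sum(sv$nCaught)
  expect_gt(total, 33)             # same order as 99 juveniles
  expect_lt(total, 300)
  expect_gt(mean(sv$nCaught == 0), 0.9)
})

test_that("uniform true density yields uniform sighting frequencies", {
  sc <- smallScene()
  env <- smallEnv()
  sgt <- simulateSightings(sc, env, flatTrueModel(), n = 5000, seed = 31)
  z <- cellTable(sc)
  valid <- z$microgrid[z$water & z$Min_Depth <= 3 & z$Min_Depth > 0]
  counts <- table(factor(sgt$microgrid, levels = valid))
  expect_gt(stats::chisq.test(counts)$p.value, 0.001)
})

test_that("density concentrated in one cell sends every sighting there", {
  sc <- smallScene()
  z <- cellTable(sc)
  valid <- z[z$water & z$Min_Depth <= 3 & z$Min_Depth > 0, ]
  tab <- table(valid$Sum_MNN)
  v <- as.numeric(names(tab)[tab == 1][1])   # a uniquely held focal value
  target <- valid$microgrid[valid$Sum_MNN == v]
  spike <- defaultTrueModel(
    fTemp = function(x) 0 * x, fDO = function(x) 0 * x,
    fSalin = function(x) 0 * x, fYear = function(y) 0 * y,
    fDist = function(d) 0 * d, betaDeveloped = 0,
    fMNN = function(x) ifelse(x == v, 40, 0))
  sgt <- simulateSightings(sc, smallEnv(), spike, n = 200, seed = 32)
  expect_true(all(sgt$microgrid == target))
})

test_that("sighting frequencies are proportional to density", {
  sc <- smallScene()
  env <- smallEnv()
  grad <- defaultTrueModel(
    fTemp = function(x) 0 * x, fDO = function(x) 0 * x,
    fSalin = function(x) 0 * x, fYear = function(y) 0 * y,
    fDist = function(d) 0 * d, betaDeveloped = 0,
    fMNN = function(x) 0.005 * x)
  n <- 10000
  sgt <- simulateSightings(sc, env, grad, n = n, seed = 33)
  z <- cellTable(sc)
  valid <- z[z$water & z$Min_Depth <= 3 & z$Min_Depth > 0, ]
  w <- exp(0.005 * valid$Sum_MNN)
  expected <- n * w / sum(w)
  observed <- as.numeric(table(factor(sgt$microgrid,
                                      levels = valid$microgrid)))
  slope <- sum(observed * expected) / sum(expected^2)  # through origin
  expect_lt(abs(slope - 1), 0.05)
  expect_gt(cor(observed, expected), 0.95)
})

test_that("degenerate sighting requests are rejected", {
  expect_error(simulateSightings(smallScene(), smallEnv(),
                                 flatTrueModel(), n = 0, seed = 1),
               ">= 1")
})
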