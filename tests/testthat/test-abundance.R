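test_that("prediction grid honours both clip rules and reports areas", {
  sc <- smallScene()
  sv <- smallSurvey()
  grid <- buildPredictionGrid(sc, sv)
  g <- cellTable(grid)
  expect_true(all(g$Min_Depth <= 3))
  expect_true(all(g$soakAreaYd2 > 0))
  expect_true(any(g$inUniverse))
  # cells entirely beyond 61 m of shore are excluded
  sub <- sc@config$subres
  for (i in seq_len(min(nrow(g), 20))) {
    px <- (g$ix[i] - 1) * sub + seq_len(sub)
    py <- (g$iy[i] - 1) * sub + seq_len(sub)
    expect_true(any(sc@distShorePix[px, py] <= 61))
  }
  # a depth exactly at the boundary is retained; strictly deeper is removed
  sc2 <- sc
  victim <- match(g$microgrid[1], sc2@zonal$microgrid)
  sc2@zonal$Min_Depth[victim] <- 3.0
  expect_true(g$microgrid[1] %in%
                cellTable(buildPredictionGrid(sc2, sv))$microgrid)
  sc2@zonal$Min_Depth[victim] <- 3.0001
  expect_false(g$microgrid[1] %in%
                 cellTable(buildPredictionGrid(sc2, sv))$microgrid)
  expect_error(buildPredictionGrid(sc, sv, maxDepthM = -1), "empty")
})

test_that("grid soak areas agree with an independent pixel count", {
  sc <- smallScene()
  grid <- buildPredictionGrid(sc, smallSurvey())
  g <- cellTable(grid)
  sub <- sc@config$subres
  ps <- sc@pixelSize
  M2YD <- 1.0936133
  for (i in sample(nrow(g), 10)) {
    px <- (g$ix[i] - 1) * sub + seq_len(sub)
    py <- (g$iy[i] - 1) * sub + seq_len(sub)
    nIn <- sum(sc@distShorePix[px, py] <= 61)
    expect_equal(g$soakAreaYd2[i], nIn * ps^2 * M2YD^2, tolerance = 1e-9)
  }
})

test_that("gaussian posterior draws match the fit's moments", {
  f <- smallFit()
  dr <- samplePosterior(f, n = 10000, seed = 5, sampler = "gaussian")
  b <- coef(f@fit); V <- f@fit$Vp
  se <- sqrt(diag(V) / nrow(dr))
  expect_true(all(abs(colMeans(dr) - b) < 4 * se))
  C <- cov(dr)
  tol <- 0.1 * sqrt(outer(diag(V), diag(V))) + 1e-12
  expect_true(all(abs(C - V) < 5 * tol))
  # determinism under a fixed seed
  d1 <- samplePosterior(f, n = 50, seed = 9, sampler = "gaussian")
  d2 <- samplePosterior(f, n = 50, seed = 9, sampler = "gaussian")
  expect_identical(d1, d2)
  m1 <- samplePosterior(f, n = 50, seed = 9, sampler = "mh")
  m2 <- samplePosterior(f, n = 50, seed = 9, sampler = "mh")
  expect_identical(m1, m2)
  expect_equal(dim(m1), c(50L, length(b)))
})

test_that("constant density integrates to density times area exactly", {
  set.seed(31)
  d <- data.frame(effort = runif(400, 5e3, 2e4))
  d$nCaught <- round(rtweedie(400, mu = d$effort * 2e-5, p = 1.5, phi = 1))
  f <- fitDensityModel(modelSpec(character(0)), d)
  grid <- buildPredictionGrid(smallScene(), smallSurvey())
  g <- cellTable(grid)
  b0 <- unname(coef(f@fit)[1])
  draws <- matrix(b0, nrow = 3, ncol = 1)   # zero coefficient variance
  ad <- estimateAbundance(draws, f, grid, smallEnv(), years = 2010,
                          seasons = "Spring/Summer")
  expected <- exp(b0) * 60 * sum(g$soakAreaYd2)
  tot <- ad@draws[, 1, 1, "full"]
  expect_equal(tot, rep(expected, 3), tolerance = 1e-10)
  expect_equal(sd(tot), 0)
  expect_equal(ad@draws[, 1, 1, "sampled"],
               rep(exp(b0) * 60 * sum(g$soakAreaYd2[g$inUniverse]), 3),
               tolerance = 1e-10)
})

test_that("sampled-domain totals never exceed full-domain totals", {
  f <- smallFit()
  grid <- buildPredictionGrid(smallScene(), smallSurvey())
  dr <- samplePosterior(f, n = 40, seed = 6, sampler = "gaussian")
  ad <- estimateAbundance(dr, f, grid, smallEnv(), years = 2010:2011)
  for (yi in 1:2) for (si in 1:2)
    expect_true(all(ad@draws[, yi, si, "sampled"] <=
                      ad@draws[, yi, si, "full"] + 1e-9))
  expect_true(all(ad@draws[ad@retained] > 0))
})

test_that("infinite trim factor is a no-op and trimming masks extremes", {
  f <- smallFit()
  grid <- buildPredictionGrid(smallScene(), smallSurvey())
  dr <- samplePosterior(f, n = 60, seed = 7, sampler = "gaussian")
  adInf <- estimateAbundance(dr, f, grid, smallEnv(), years = 2010,
                             trimFactor = Inf)
  expect_true(all(adInf@retained))
  adTrim <- estimateAbundance(dr, f, grid, smallEnv(), years = 2010,
                              trimFactor = 100)
  expect_identical(adInf@draws, adTrim@draws)
  # a manually injected extreme draw is masked
  dr2 <- dr
  dr2[1, 1] <- dr2[1, 1] + 20      # e^20-fold density explosion
  adX <- estimateAbundance(dr2, f, grid, smallEnv(), years = 2010,
                           trimFactor = 100)
  expect_false(adX@retained[1, 1, 1, "full"])
  s <- summarizeAbundance(adX)
  expect_true(all(s$nRetained < nrow(dr2)))
})

test_that("interannual comparison reproduces textbook Tukey arithmetic", {
  set.seed(41)
  nd <- 40
  vals <- cbind(rnorm(nd, 100, 8), rnorm(nd, 70, 8), rnorm(nd, 99, 8))
  arr <- array(vals, dim = c(nd, 3, 1, 1),
               dimnames = list(NULL, 2010:2012, "Spring/Summer", "sampled"))
  ad <- new("AbundanceDraws", draws = arr,
            retained = array(TRUE, dim = dim(arr), dimnames = dimnames(arr)),
            years = 2010:2012, seasons = "Spring/Summer",
            domains = "sampled", trimFactor = Inf, meta = list())
  cmp <- compareYears(ad, domain = "sampled")
  # textbook Tukey: q = |mean_i - mean_j| / sqrt(MSE / n)
  mse <- sum((vals - rep(colMeans(vals), each = nd))^2) / (3 * nd - 3)
  qStat <- abs(outer(colMeans(vals), colMeans(vals), "-")) / sqrt(mse / nd)
  pTuk <- 1 - ptukey(qStat, nmeans = 3, df = 3 * nd - 3)
  tuk <- TukeyHSD(cmp$anova)$year
  expect_equal(unname(tuk[, "p adj"]),
               unname(pTuk[cbind(c(2, 3, 3), c(1, 1, 2))]),
               tolerance = 1e-8)
  # well-separated and indistinguishable years get the right letters
  lets <- cmp$letters
  expect_false(lets$letters[lets$year == 2010] ==
                 lets$letters[lets$year == 2011])
  expect_true(any(duplicated(lets$letters)) ||
                lets$letters[lets$year == 2010] ==
                  lets$letters[lets$year == 2012])
})

test_that("identical yearly distributions share one letter", {
  set.seed(42)
  nd <- 30
  arr <- array(rnorm(nd * 3, 50, 5), dim = c(nd, 3, 1, 1),
               dimnames = list(NULL, 2010:2012, "Spring/Summer", "sampled"))
  ad <- new("AbundanceDraws", draws = arr,
            retained = array(TRUE, dim = dim(arr), dimnames = dimnames(arr)),
            years = 2010:2012, seasons = "Spring/Summer",
            domains = "sampled", trimFactor = Inf, meta = list())
  lets <- compareYears(ad, domain = "sampled")$letters
  expect_equal(length(unique(lets$letters)), 1L)
})

test_that("interannual change ratios and their summary are exact", {
  r <- interannualChange(setNames(c(100, 50, 50), 2010:2012))
  expect_equal(unname(r$ratios), c(0.5, 1.0))
  expect_equal(r$mean, 0.75)
  const <- interannualChange(setNames(rep(7, 4), 2010:2013))
  expect_true(all(const$ratios == 1))
  set.seed(8)
  v <- setNames(runif(6, 10, 100), 2010:2015)
  rr <- interannualChange(v)
  expect_equal(unname(rr$ratios), unname(v[-1] / v[-6]), tolerance = 1e-12)
  expect_equal(rr$sd, sd(v[-1] / v[-6]), tolerance = 1e-12)
  expect_error(interannualChange(setNames(c(1, 0), 2010:2011)), "zero")
  expect_error(interannualChange(setNames(1, 2010)), "at least 2")
})
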