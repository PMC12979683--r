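test_that("effort is minutes times net area in square yards", {
  # a net whose area is exactly 100 yd^2
  L <- 10; H <- 10 / 1.0936133^2
  expect_equal(computeEffort(minutes = 60, netLengthM = L, netHeightM = H),
               6000, tolerance = 1e-10)
  # linear in duration
  expect_equal(computeEffort(minutes = 30, netLengthM = 61, netHeightM = 2.5),
               computeEffort(minutes = 60, netLengthM = 61,
                             netHeightM = 2.5) / 2)
  # unit-conversion oracle: 61 m x 2.5 m net for 60 min
  expect_equal(computeEffort(minutes = 60, netLengthM = 61, netHeightM = 2.5),
               60 * (61 * 1.09361) * (2.5 * 1.09361), tolerance = 1e-4)
  t0 <- as.POSIXct("2015-06-01 08:00:00", tz = "UTC")
  expect_equal(computeEffort(t0, t0 + 3600, 61, 2.5),
               computeEffort(minutes = 60, netLengthM = 61,
                             netHeightM = 2.5))
  expect_error(computeEffort(t0, t0, 61, 2.5), "positive")
  expect_error(computeEffort(minutes = 60, netLengthM = 0, netHeightM = 2),
               "positive")
})

test_that("season assignment splits the year March-August vs the rest", {
  expect_equal(as.character(assignSeason(as.Date("2015-03-01"))),
               "Spring/Summer")
  expect_equal(as.character(assignSeason(as.Date("2015-08-31"))),
               "Spring/Summer")
  expect_equal(as.character(assignSeason(as.Date("2015-09-01"))),
               "Fall/Winter")
  expect_equal(as.character(assignSeason(as.Date("2015-02-28"))),
               "Fall/Winter")
  months <- assignSeason(seq(as.Date("2015-01-15"), by = "month",
                             length.out = 12))
  expect_equal(as.vector(table(months)), c(6, 6))
})

test_that("juvenile filter keeps 1.86 m inclusively", {
  fish <- data.frame(stl = c(0.8, 1.3, 1.86, 2.0, 2.2))
  expect_equal(nrow(filterJuveniles(fish)), 3)
  expect_true(1.86 %in% filterJuveniles(fish)$stl)
  expect_false(1.87 %in% filterJuveniles(data.frame(stl = 1.87))$stl)
  expect_warning(out <- filterJuveniles(data.frame(stl = c(1, NA))),
                 "missing STL")
  expect_equal(nrow(out), 1)
})

test_that("age classes follow the sex-specific length thresholds", {
  expect_equal(assignAgeClass(1.37, "F"), "age0")
  expect_equal(assignAgeClass(1.34, "M"), "age1")   # strict inequality
  expect_equal(assignAgeClass(1.33, "M"), "age0")
  expect_equal(assignAgeClass(1.90, "M"), "older")
  expect_message(unk <- assignAgeClass(c(1.35, 1.37), c("?", "?")),
                 "midpoint")
  expect_equal(unk, c("age0", "age1"))
  # classes partition: every fish in exactly one class
  set.seed(3)
  stl <- runif(500, 0.5, 2.5)
  sex <- sample(c("M", "F"), 500, replace = TRUE)
  cls <- assignAgeClass(stl, sex)
  expect_true(all(cls %in% c("age0", "age1", "older")))
  # juvenile filter composed with ageing never yields "older"
  juv <- filterJuveniles(data.frame(stl = stl, sex = sex))
  expect_false("older" %in% assignAgeClass(juv$stl, juv$sex))
})

test_that("CPUE arithmetic: scale invariance and empty groups", {
  eff <- data.frame(Year = c(2010, 2010, 2011), effort = c(4e5, 6e5, 1e6))
  ct <- data.frame(Year = 2010, n = 1)
  out <- cpue(ct, eff, by = "Year")
  expect_equal(out$cpue[out$Year == 2010], 1.0)   # 1 fish per 1e6 yard-min
  expect_equal(out$cpue[out$Year == 2011], 0)     # empty group -> 0
  dbl <- cpue(data.frame(Year = 2010, n = 2),
              transform(eff, effort = effort * 2), by = "Year")
  expect_equal(dbl$cpue[dbl$Year == 2010], out$cpue[out$Year == 2010])
  # spreadsheet-style recomputation on a random table
  set.seed(9)
  eff2 <- data.frame(Year = rep(2010:2012, each = 20),
                     effort = runif(60, 5e3, 2e4))
  ct2 <- data.frame(Year = sample(2010:2012, 15, replace = TRUE),
                    n = rpois(15, 2))
  out2 <- cpue(ct2, eff2, by = "Year")
  for (y in 2010:2012) {
    manual <- sum(ct2$n[ct2$Year == y]) / sum(eff2$effort[eff2$Year == y]) *
      1e6
    expect_equal(out2$cpue[out2$Year == y], manual, tolerance = 1e-12)
  }
  expect_error(cpue(ct, data.frame(Year = 2010, effort = 0), by = "Year"),
               "positive")
})

test_that("age-structured CPUE sums to per-fish counts", {
  sv <- smallSurvey()
  byAge <- cpueByAge(sv)
  expect_setequal(unique(byAge$ageClass), c("age0", "age1"))
  expect_equal(sum(byAge$n), sum(sv$nCaught))
})

test_that("kriging interpolator is exact, handles constants and gradients", {
  sc <- smallScene()
  set.seed(21)
  z <- cellTable(sc)
  wc <- z[z$water, ]
  pts <- wc[sample(nrow(wc), 50), ]
  # constant observations -> constant field
  obs <- data.frame(date = as.Date("2010-05-01"), x = pts$x, y = pts$y,
                    value = 5)
  fld <- interpolateEnvironment(obs, sc)[[1]]
  expect_true(all(abs(fld - 5) < 1e-6, na.rm = TRUE))
  # exact at observation cells for zero nugget
  obs$value <- runif(50, 10, 20)
  fld <- interpolateEnvironment(obs, sc)[[1]]
  at <- fld[cbind(pts$ix, pts$iy)]
  expect_equal(at, obs$value, tolerance = 1e-6)
  # linear-gradient truth recovered within 5% of its range
  truthf <- function(x, y) 10 + (x + y) / 800
  obs$value <- truthf(pts$x, pts$y)
  fld <- interpolateEnvironment(obs, sc)[[1]]
  truth <- truthf(matrix(sc@cellX[row(sc@water)], sc@nx, sc@ny),
                  matrix(sc@cellY[col(sc@water)], sc@nx, sc@ny))
  err <- sqrt(mean((fld - truth)^2, na.rm = TRUE))
  expect_lt(err, 0.05 * diff(range(truth)))
  # too few points on a day falls back to a season mean with a warning
  short <- data.frame(date = as.Date("2010-05-02"), x = pts$x[1:2],
                      y = pts$y[1:2], value = c(1, 3))
  expect_warning(fb <- interpolateEnvironment(rbind(obs, short), sc),
                 "season-mean")
  expect_true(all(abs(fb[["2010-05-02"]] - mean(c(obs$value, 1, 3))) < 1e-9,
                  na.rm = TRUE))
})
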