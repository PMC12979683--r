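# brute-force oracles for the raster toolkit (see also helper-oracles.R)

gaussianImage <- function(nx, ny, mus, sds, labels, seed) {
  set.seed(seed)
  img <- array(0, dim = c(nx, ny, length(mus[[1]])))
  lab <- matrix(sample(labels, nx * ny, replace = TRUE), nx, ny)
  for (b in seq_len(dim(img)[3]))
    for (cl in labels)
      img[, , b][lab == cl] <- rnorm(sum(lab == cl), mus[[cl]][b],
                                     sds[[cl]][b])
  list(img = img, lab = lab)
}

test_that("focal sums match the nested-loop oracle on random masks", {
  set.seed(91)
  for (rep in 1:3) {
    m <- matrix(as.integer(runif(16 * 16) < 0.4), 16, 16)
    expect_identical(mangroveFocalSum(m), bruteFocalSum(m))
  }
})

test_that("focal sums hit the documented extremes", {
  full <- matrix(1L, 12, 12)
  fs <- mangroveFocalSum(full)
  expect_equal(fs[6, 6], 64)            # interior of continuous cover
  iso <- matrix(0L, 9, 9); iso[5, 5] <- 1L
  expect_equal(mangroveFocalSum(iso)[5, 5], 1)
  expect_true(all(is.na(mangroveFocalSum(iso)[iso == 0])))
  rng <- mangroveFocalSum(matrix(as.integer(runif(256) < 0.5), 16, 16))
  expect_true(all(rng >= 1 & rng <= 64, na.rm = TRUE))
})

test_that("focal sum totals are invariant under raster translation", {
  set.seed(17)
  core <- matrix(as.integer(runif(64) < 0.5), 8, 8)
  total <- function(offx, offy) {
    canvas <- matrix(0L, 30, 30)
    canvas[offx + 1:8, offy + 1:8] <- core
    sum(mangroveFocalSum(canvas), na.rm = TRUE)
  }
  expect_identical(total(6, 6), total(12, 9))
})

test_that("training signatures recover known class Gaussians", {
  mus <- list(mangrove = c(10, 50), other_vegetation = c(40, 45),
              non_vegetation = c(80, 10))
  sds <- list(mangrove = c(3, 3), other_vegetation = c(3, 3),
              non_vegetation = c(3, 3))
  g <- gaussianImage(30, 30, mus, sds, names(mus), seed = 5)
  set.seed(6)
  pts <- do.call(rbind, lapply(names(mus), function(cl) {
    idx <- which(g$lab == cl, arr.ind = TRUE)
    idx <- idx[sample(nrow(idx), 30), ]     # 30 training points per class
    data.frame(x = idx[, 1] - 0.5, y = idx[, 2] - 0.5, class = cl)
  }))
  sig <- trainSignatures(g$img, pts)
  for (cl in names(mus)) {
    se <- sds[[cl]] / sqrt(30)
    expect_true(all(abs(sig[[cl]]@mean - mus[[cl]]) < 3 * se))
    expect_equal(sig[[cl]]@n, 30L)
  }
})

test_that("degenerate training classes get a ridge and keep their mean", {
  img <- array(7, dim = c(6, 6, 2))
  img[, , 2] <- 3
  pts <- data.frame(x = rep(seq(0.5, 5.5, 1), 2),
                    y = rep(c(0.5, 1.5), each = 6),
                    class = rep(c("mangrove", "other_vegetation"),
                                each = 6))
  msgs <- capture_messages(sig <- trainSignatures(img, pts))
  expect_true(any(grepl("ridge applied", msgs)))
  expect_equal(sig[["mangrove"]]@mean, c(7, 3))
  ev <- eigen(sig[["mangrove"]]@cov, only.values = TRUE)$values
  expect_true(all(ev > 0))
})

test_that("equal priors and spherical equal covariances reduce to nearest mean", {
  set.seed(8)
  img <- array(runif(10 * 10 * 2, 0, 100), dim = c(10, 10, 2))
  mus <- list(mangrove = c(20, 20), other_vegetation = c(50, 60),
              non_vegetation = c(85, 30))
  sig <- lapply(names(mus), function(cl)
    new("ClassSignature", label = cl, mean = mus[[cl]],
        cov = diag(2) * 16, n = 30L))
  names(sig) <- names(mus)
  cl <- classifyMLC(img, sig)
  nearest <- apply(matrix(img, 100, 2), 1, function(v)
    names(mus)[which.min(vapply(mus, function(m) sum((v - m)^2),
                                numeric(1)))])
  expect_identical(as.vector(cl$class), nearest)
  # uniform priors invariant to a constant multiple
  cl2 <- classifyMLC(img, sig, priors = c(5, 5, 5))
  expect_identical(cl$class, cl2$class)
})

test_that("urban priors override equal likelihoods (0.02 < 0.49)", {
  mus <- list(mangrove = c(10, 10), other_vegetation = c(10, 10),
              non_vegetation = c(10, 10))
  sig <- lapply(names(mus), function(cl)
    new("ClassSignature", label = cl, mean = mus[[cl]], cov = diag(2),
        n = 10L))
  names(sig) <- names(mus)
  img <- array(10, dim = c(1, 1, 2))
  urban <- matrix(TRUE, 1, 1)
  res <- classifyMLC(img, sig, priors = makePriorMap(urban))
  expect_false(res$class[1, 1] == "mangrove")
  expect_true(is.na(res$mangrove[1, 1]))
})

test_that("two-run urban/non-urban protocol equals one composite-prior run", {
  set.seed(9)
  img <- array(rnorm(12 * 12 * 3, 50, 20), dim = c(12, 12, 3))
  mus <- list(mangrove = c(30, 60, 40), other_vegetation = c(55, 45, 60),
              non_vegetation = c(70, 30, 20))
  sig <- lapply(names(mus), function(cl)
    new("ClassSignature", label = cl, mean = mus[[cl]],
        cov = diag(3) * 100, n = 30L))
  names(sig) <- names(mus)
  urban <- matrix(runif(144) < 0.3, 12, 12)
  composite <- classifyMLC(img, sig, priors = makePriorMap(urban))
  urbanOnly <- classifyMLC(img, sig, priors = c(0.02, 0.49, 0.49))
  nonUrban <- classifyMLC(img, sig, priors = c(1, 1, 1) / 3)
  merged <- nonUrban$class
  merged[urban] <- urbanOnly$class[urban]
  expect_identical(composite$class, merged)
})

test_that("all-zero priors are an error", {
  sig <- list(mangrove = new("ClassSignature", label = "mangrove",
                             mean = 1, cov = matrix(1), n = 2L))
  pr <- array(0, dim = c(2, 2, 1))
  expect_error(classifyMLC(array(1, dim = c(2, 2, 1)), sig, priors = pr),
               "all-zero priors")
})

test_that("mangrove shoreline distances match a densified brute force", {
  # shoreline along y = 10.25 m; 1-m pixels
  shore <- matrix(c(0, 10.25, 20, 10.25), 1, 4)
  m <- matrix(1L, 20, 20)
  d <- mangroveDistanceToShore(m, shore, bufferM = 10, pixelSize = 1)
  # a cell whose centre sits nearly on the line
  expect_equal(d[5, 11], 0.25)
  expect_equal(d[3, 1], 9.75)      # near the buffer edge, still kept
  dense <- cbind(seq(0, 20, by = 0.01), 10.25)
  idx <- which(!is.na(d), arr.ind = TRUE)
  for (k in sample(nrow(idx), 10)) {
    px <- idx[k, 1] - 0.5; py <- idx[k, 2] - 0.5
    brute <- min(sqrt((dense[, 1] - px)^2 + (dense[, 2] - py)^2))
    expect_lt(abs(d[idx[k, 1], idx[k, 2]] - brute), 0.5)
  }
  expect_error(mangroveDistanceToShore(m, matrix(numeric(0), 0, 4)),
               "nonempty")
})

test_that("distance buffer boundary excludes cells just outside", {
  shore <- matrix(c(0, 0, 10, 0), 1, 4)
  m <- matrix(1L, 10, 15)
  d <- mangroveDistanceToShore(m, shore, bufferM = 10, pixelSize = 1)
  expect_equal(d[5, 10], 9.5)          # inside the buffer
  expect_true(is.na(d[5, 11]))         # 10.5 m away: outside
})

test_that("zonal statistics conserve totals and handle empty zones", {
  set.seed(12)
  m <- matrix(as.integer(runif(256) < 0.3), 16, 16)
  m[1:8, 1:8] <- 0L                     # an entirely mangrove-free zone
  fs <- mangroveFocalSum(m)
  shore <- matrix(c(0, 0, 16, 0), 1, 4)
  dd <- mangroveDistanceToShore(m, shore, bufferM = Inf, pixelSize = 1)
  zones <- matrix(rep(rep(1:2, each = 8), 16), 16, 16)
  zones[, 9:16] <- zones[, 9:16] + 2L
  zt <- zonalStats(dd, fs, zones)
  expect_equal(sum(zt$Sum_MNN), sum(fs, na.rm = TRUE))
  expect_equal(zt$Sum_MNN[zt$zone == 1], 0)
  expect_true(is.na(zt$Min_MDTS[zt$zone == 1]))
  for (z in 2:4) {
    expect_equal(zt$Min_MDTS[zt$zone == z],
                 min(dd[zones == z], na.rm = TRUE))
    expect_equal(zt$Sum_MNN[zt$zone == z], sum(fs[zones == z], na.rm = TRUE))
  }
})
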