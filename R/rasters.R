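# Habitat covariate construction from rasters: supervised maximum-likelihood
# classification, distance to shoreline, focal mangrove sums and zonal
# statistics. Rasters are plain numeric matrices indexed [ix, iy] with cell
# centres at ((i - 0.5) * pixelSize) in a projected plane (metres).

#' Train per-class multiband signatures
#'
#' Estimates the per-band mean vector and band covariance matrix of each
#' land-cover class from labelled training points, the inputs the
#' maximum-likelihood classifier needs. Degenerate classes (identical
#' pixels, or any near-singular covariance) are regularized by adding a
#' ridge of `ridge * trace / nbands` to the diagonal (or `ridge` itself if
#' the trace is zero), with a message.
#'
#' @param image 3-d array `[nx, ny, band]` of band values.
#' @param trainingPoints data.frame with columns `x`, `y` (metres) and
#'   `class`; at least `nbands + 1` points per class, all within the image.
#' @param pixelSize pixel side (m).
#' @param origin coordinates of the image's lower-left corner.
#' @param ridge relative ridge for degenerate covariances.
#' @return named list of [ClassSignature-class] objects.
#' @export
trainSignatures <- function(image, trainingPoints, pixelSize = 1,
                            origin = c(0, 0), ridge = 1e-6) {
  stopifnot(length(dim(image)) == 3L)
  nb <- dim(image)[3]
  ixp <- floor((trainingPoints$x - origin[1]) / pixelSize) + 1L
  iyp <- floor((trainingPoints$y - origin[2]) / pixelSize) + 1L
  if (any(ixp < 1L | ixp > dim(image)[1] | iyp < 1L | iyp > dim(image)[2]))
    stop("training points outside image extent")
  vals <- sapply(seq_len(nb), function(b) image[cbind(ixp, iyp, b)])
  vals <- matrix(vals, ncol = nb)
  out <- list()
  for (cl in unique(as.character(trainingPoints$class))) {
    v <- vals[trainingPoints$class == cl, , drop = FALSE]
    if (nrow(v) < nb + 1L)
      stop("class '", cl, "' needs at least ", nb + 1L, " training points")
    mu <- colMeans(v)
    S <- stats::cov(v)
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-10 * max(ev, 1e-12)) {
      lam <- if (sum(diag(S)) > 0) ridge * sum(diag(S)) / nb else ridge
      S <- S + diag(lam, nb)
      message("covariance for class '", cl, "' was singular; ridge applied")
    }
    out[[cl]] <- new("ClassSignature", label = cl, mean = unname(mu),
                     cov = unname(S), n = nrow(v))
  }
  out
}

#' Build an a-priori probability map over the three classes
#'
#' Outside urban pixels all three classes have equal priors. In urban
#' pixels the mangrove prior is reduced (default 2%) and the other two
#' classes split the remainder equally, which suppresses lawns and
#' landscape vegetation classifying as mangroves.
#'
#' @param urbanMask logical matrix: TRUE for urban pixels.
#' @param classes class labels; the first is the mangrove class.
#' @param mangrovePriorUrban mangrove prior inside urban pixels.
#' @return array `[nx, ny, class]` of priors summing to 1 at every pixel.
#' @export
makePriorMap <- function(urbanMask,
                         classes = c("mangrove", "other_vegetation",
                                     "non_vegetation"),
                         mangrovePriorUrban = 0.02) {
  nx <- nrow(urbanMask); ny <- ncol(urbanMask)
  pr <- array(1 / length(classes), dim = c(nx, ny, length(classes)),
              dimnames = list(NULL, NULL, classes))
  rest <- (1 - mangrovePriorUrban) / (length(classes) - 1L)
  pr[, , 1][urbanMask] <- mangrovePriorUrban
  for (k in seq_along(classes)[-1]) pr[, , k][urbanMask] <- rest
  pr
}

#' Maximum-likelihood classification with a-priori weights
#'
#' Assigns each pixel the class maximizing the Gaussian log-likelihood of
#' its band vector plus the log prior:
#' `argmax_c log N(x; mu_c, Sigma_c) + log prior_c(pixel)`. The mangrove
#' output sets all non-mangrove pixels to `NA`.
#'
#' @param image 3-d array `[nx, ny, band]`.
#' @param signatures list of [ClassSignature-class] covering all classes.
#' @param priors either a numeric vector of per-class priors (constant over
#'   pixels) or an array from [makePriorMap()]. Any pixel whose priors are
#'   all zero is an error.
#' @return list with `class` (character matrix of labels) and `mangrove`
#'   (matrix: 1 where classified mangrove, `NA` elsewhere).
#' @export
classifyMLC <- function(image, signatures, priors = NULL) {
  stopifnot(length(dim(image)) == 3L)
  nx <- dim(image)[1]; ny <- dim(image)[2]; nb <- dim(image)[3]
  cls <- names(signatures)
  nc <- length(cls)
  if (is.null(priors)) priors <- rep(1 / nc, nc)
  if (is.numeric(priors) && is.null(dim(priors)))
    priors <- array(rep(priors, each = nx * ny), dim = c(nx, ny, nc),
                    dimnames = list(NULL, NULL, cls))
  psum <- apply(priors, c(1, 2), sum)
  if (any(psum == 0)) stop("pixel with all-zero priors")
  X <- matrix(image, nx * ny, nb)
  score <- matrix(NA_real_, nx * ny, nc)
  for (k in seq_len(nc)) {
    sig <- signatures[[k]]
    Si <- solve(sig@cov)
    ld <- determinant(sig@cov, logarithm = TRUE)$modulus
    centered <- sweep(X, 2, sig@mean)
    maha <- rowSums((centered %*% Si) * centered)
    score[, k] <- -0.5 * as.numeric(ld) - 0.5 * maha +
      log(as.vector(priors[, , k]))
  }
  idx <- max.col(score, ties.method = "first")
  classMat <- matrix(cls[idx], nx, ny)
  mangrove <- matrix(NA_real_, nx, ny)
  mangrove[classMat == cls[1]] <- 1
  list(class = classMat, mangrove = mangrove)
}

#' Distance from mangrove cells to the shoreline
#'
#' Euclidean distance from each mangrove pixel centre to the nearest point
#' on the shoreline (point-to-segment, so distances interpolate along
#' segments, not just to vertices). Pixels beyond the buffer, and
#' non-mangrove pixels, are `NA`.
#'
#' @param mangrove matrix where mangrove pixels are 1 (anything else,
#'   including `NA` and 0, is not mangrove).
#' @param shoreline 4-column segment matrix (x1, y1, x2, y2), nonempty.
#' @param bufferM keep only distances within this buffer of the shoreline
#'   (default 10 m).
#' @param pixelSize pixel side (m).
#' @param origin lower-left corner coordinates.
#' @return matrix of distances (m) with `NA` outside mangroves or buffer.
#' @export
mangroveDistanceToShore <- function(mangrove, shoreline, bufferM = 10,
                                    pixelSize = 1, origin = c(0, 0)) {
  if (is.null(nrow(shoreline)) || nrow(shoreline) == 0L)
    stop("shoreline must be nonempty")
  idx <- which(!is.na(mangrove) & mangrove == 1, arr.ind = TRUE)
  out <- matrix(NA_real_, nrow(mangrove), ncol(mangrove))
  if (nrow(idx) == 0L) return(out)
  px <- origin[1] + (idx[, 1] - 0.5) * pixelSize
  py <- origin[2] + (idx[, 2] - 0.5) * pixelSize
  d <- distToSegments(px, py, shoreline)
  d[d > bufferM] <- NA_real_
  out[idx] <- d
  out
}

#' Focal sum of mangrove cells in an 8 x 8 neighbourhood
#'
#' For each mangrove cell, counts the mangrove cells inside its 8 x 8
#' window. An even window has no centre cell; the focal cell sits at
#' position (4, 4) of the window (0-indexed offsets -4..+3 in both axes),
#' the convention of common focal-statistics tools. Cells outside the
#' raster count as non-mangrove, so values run from 1 (isolated mangrove)
#' to 64 (continuous cover). Non-mangrove cells are `NA`.
#'
#' @param mangrove binary matrix (1 = mangrove; 0 or `NA` otherwise).
#' @return integer matrix of focal sums, `NA` off-mangrove.
#' @export
mangroveFocalSum <- function(mangrove) {
  m <- mangrove
  m[is.na(m)] <- 0
  if (!all(m %in% c(0, 1))) stop("'mangrove' must be binary")
  nx <- nrow(m); ny <- ncol(m)
  pad <- matrix(0L, nx + 7L, ny + 7L)
  pad[5:(nx + 4), 5:(ny + 4)] <- m   # focal cell at window offset (-4..+3)
  s <- matrix(0L, nx, ny)
  for (dx in -4:3) for (dy in -4:3)
    s <- s + pad[(5 + dx):(nx + 4 + dx), (5 + dy):(ny + 4 + dy)]
  s[m == 0] <- NA_integer_
  matrix(as.integer(s), nx, ny)
}

#' Zonal statistics of habitat rasters onto micro-grids
#'
#' Aggregates the mangrove distance-to-shore and focal-sum rasters onto
#' zones (micro-grid membership of each pixel): per zone the minimum
#' distance (`Min_MDTS`, `NA` when the zone has no mangrove) and the sum of
#' focal values (`Sum_MNN`, 0 when the zone has no mangrove, so it enters
#' the model as "no mangrove habitat").
#'
#' @param distRaster matrix from [mangroveDistanceToShore()].
#' @param focalRaster matrix from [mangroveFocalSum()].
#' @param zones integer matrix of zone ids, same dimensions.
#' @param allZones optional vector of zone ids to report even if empty.
#' @return data.frame with columns zone, Min_MDTS, Sum_MNN.
#' @export
zonalStats <- function(distRaster, focalRaster, zones, allZones = NULL) {
  stopifnot(identical(dim(distRaster), dim(zones)),
            identical(dim(focalRaster), dim(zones)))
  z <- as.vector(zones)
  ids <- sort(unique(c(z, allZones)))
  dmin <- tapply(as.vector(distRaster), z, function(v)
    if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE))
  fsum <- tapply(as.vector(focalRaster), z, function(v)
    sum(v, na.rm = TRUE))
  out <- data.frame(zone = ids,
                    Min_MDTS = as.numeric(dmin[as.character(ids)]),
                    Sum_MNN = as.numeric(fsum[as.character(ids)]))
  out$Sum_MNN[is.na(out$Sum_MNN)] <- 0
  out
}
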