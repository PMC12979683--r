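#' Configuration for the synthetic estuary scene
#'
#' Defaults describe a schematic 6 x 6 km estuary of 200-m square micro-grid
#' cells: an open harbor in the southern half fed by three linear rivers
#' (A, B, C) entering from the north, with mangrove cover concentrated along
#' shorelines and river mouths and depth shoaling toward shore. Geometry is
#' deliberately schematic (rectangular harbor, straight rivers): the
#' statistics downstream depend on covariate structure, not cartography.
#'
#' @param nx,ny grid dimensions in cells (each >= 4).
#' @param cellSize cell side (m), > 0; 200 m mirrors survey micro-grids.
#' @param subres sub-cell resolution factor for the mangrove raster
#'   (pixel size = cellSize / subres).
#' @param riverFrac named x-positions of river centrelines as fractions of
#'   the domain width; at least one river.
#' @param riverHalfWidth river half-width in cells (channel = 2w + 1 cells).
#' @param mouthRow row index separating harbor (<=) from river zone (>).
#' @param mangroveFraction peak mangrove cover probability at the shoreline;
#'   0 produces a mangrove-free scene.
#' @param developedRiver river whose mouth neighbourhood is flagged as
#'   developed shoreline (NULL for none).
#' @param maxDepth maximum harbor depth (m).
#' @param epoch first valid date for environmental simulation.
#' @return a configuration list for [generateScene()].
#' @export
estuaryConfig <- function(nx = 30L, ny = 30L, cellSize = 200, subres = 10L,
                          riverFrac = c(A = 0.2, B = 0.5, C = 0.8),
                          riverHalfWidth = 1L, mouthRow = NULL,
                          mangroveFraction = 0.6, developedRiver = "C",
                          maxDepth = 4.5, epoch = as.Date("2010-01-01")) {
  if (cellSize <= 0) stop("'cellSize' must be > 0")
  if (nx < 4L || ny < 4L) stop("grid must be at least 4 x 4 cells")
  if (length(riverFrac) < 1L) stop("at least one river is required")
  if (is.null(names(riverFrac)))
    names(riverFrac) <- LETTERS[seq_along(riverFrac)]
  list(nx = as.integer(nx), ny = as.integer(ny), cellSize = cellSize,
       subres = as.integer(subres), riverFrac = riverFrac,
       riverHalfWidth = as.integer(riverHalfWidth),
       mouthRow = as.integer(mouthRow %||% floor(ny / 2)),
       mangroveFraction = mangroveFraction,
       developedRiver = developedRiver, maxDepth = maxDepth,
       epoch = as.Date(epoch))
}

# minimum distance from points (px, py) to a set of segments (x1,y1,x2,y2)
distToSegments <- function(px, py, segs) {
  d2 <- rep(Inf, length(px))
  for (i in seq_len(nrow(segs))) {
    x1 <- segs[i, 1]; y1 <- segs[i, 2]; x2 <- segs[i, 3]; y2 <- segs[i, 4]
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    t <- if (len2 == 0) 0 else clip(((px - x1) * dx + (py - y1) * dy) / len2, 0, 1)
    di2 <- (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
    d2 <- pmin(d2, di2)
  }
  sqrt(d2)
}

# shoreline segments of a water mask: edges between water and land cells and
# along the domain boundary, except the southern edge (the open sea mouth)
shorelineSegments <- function(water, cellSize) {
  nx <- nrow(water); ny <- ncol(water)
  segs <- matrix(numeric(0), 0, 4)
  add <- function(x1, y1, x2, y2) segs <<- rbind(segs, c(x1, y1, x2, y2))
  for (ix in seq_len(nx)) for (iy in seq_len(ny)) {
    if (!water[ix, iy]) next
    x0 <- (ix - 1) * cellSize; x1 <- ix * cellSize
    y0 <- (iy - 1) * cellSize; y1 <- iy * cellSize
    if (ix == 1L || !water[ix - 1L, iy]) add(x0, y0, x0, y1)       # west
    if (ix == nx || !water[ix + 1L, iy]) add(x1, y0, x1, y1)       # east
    if (iy > 1L && !water[ix, iy - 1L]) add(x0, y0, x1, y0)        # south
    if (iy == ny || !water[ix, iy + 1L]) add(x0, y1, x1, y1)       # north
  }
  colnames(segs) <- c("x1", "y1", "x2", "y2")
  segs
}

#' Generate a synthetic estuary scene
#'
#' Builds an [EstuaryScene-class] from a configuration: water/land layout,
#' depth shoaling toward shore, shoreline segments, a binary mangrove raster
#' at sub-cell resolution concentrated near shorelines and river mouths,
#' per-cell river membership, signed distance to the river mouth (negative
#' seaward), a developed-shoreline flag, and the per-cell habitat covariates
#' (Min_Depth, Sum_MNN, Min_MDTS) computed through the raster toolkit
#' ([mangroveFocalSum()], [mangroveDistanceToShore()], [zonalStats()]).
#'
#' @param config from [estuaryConfig()].
#' @param seed integer seed; the scene is deterministic given (config, seed).
#' @return an [EstuaryScene-class].
#' @examples
#' sc <- generateScene(estuaryConfig(nx = 12, ny = 12), seed = 1)
#' sc
#' @export
generateScene <- function(config = estuaryConfig(), seed = 1L) {
  if (config$cellSize <= 0) stop("'cellSize' must be > 0")
  nx <- config$nx; ny <- config$ny; cs <- config$cellSize
  cellX <- (seq_len(nx) - 0.5) * cs
  cellY <- (seq_len(ny) - 0.5) * cs
  mouthRow <- config$mouthRow
  mouthY <- mouthRow * cs
  riverCols <- pmax(1L, pmin(nx, round(config$riverFrac * nx)))
  names(riverCols) <- names(config$riverFrac)

  ix <- matrix(seq_len(nx), nx, ny)
  iy <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  inChannel <- matrix(FALSE, nx, ny)
  for (rc in riverCols)
    inChannel <- inChannel | abs(ix - rc) <= config$riverHalfWidth
  water <- iy <= mouthRow | inChannel

  # nearest river (by centreline x) labels every cell
  dcol <- sapply(riverCols, function(rc) abs(seq_len(nx) - rc))
  riverOfCol <- names(riverCols)[apply(dcol, 1, which.min)]
  riverId <- matrix(riverOfCol[ix], nx, ny)

  shore <- shorelineSegments(water, cs)
  X <- matrix(cellX[ix], nx, ny); Y <- matrix(cellY[iy], nx, ny)
  distShoreCell <- matrix(distToSegments(as.vector(X), as.vector(Y), shore),
                          nx, ny)

  # depth: shoals toward shore; rivers shallower than the open harbor
  depth <- ifelse(iy > mouthRow,
                  0.25 + 2.6 * (1 - exp(-distShoreCell / 260)),
                  0.25 + (config$maxDepth - 0.25) *
                    (1 - exp(-distShoreCell / 650)))
  depth[!water] <- 0

  # signed distance to the (nearest-river) mouth point; negative seaward
  mouths <- cbind(x = cellX[riverCols], y = rep(mouthY, length(riverCols)))
  rownames(mouths) <- names(riverCols)
  mx <- mouths[riverId, "x"]
  distToRM <- matrix(sign(as.vector(Y) - mouthY) *
                       sqrt((as.vector(X) - mx)^2 + (as.vector(Y) - mouthY)^2),
                     nx, ny)

  developed <- matrix(FALSE, nx, ny)
  if (!is.null(config$developedRiver) &&
      config$developedRiver %in% names(riverCols)) {
    developed <- riverId == config$developedRiver & distShoreCell < 350 &
      iy >= mouthRow - 4L & iy <= mouthRow + 6L
  }

  ps <- cs / config$subres
  npx <- nx * config$subres; npy <- ny * config$subres
  pxX <- (seq_len(npx) - 0.5) * ps; pxY <- (seq_len(npy) - 0.5) * ps
  PX <- matrix(pxX, npx, npy); PY <- matrix(pxY, npx, npy, byrow = TRUE)
  distShorePix <- matrix(distToSegments(as.vector(PX), as.vector(PY), shore),
                         npx, npy)
  dMouthPix <- matrix(Inf, npx, npy)
  for (r in rownames(mouths)) {
    d2 <- outer((pxX - mouths[r, "x"])^2, (pxY - mouths[r, "y"])^2, "+")
    dMouthPix <- pmin(dMouthPix, sqrt(d2))
  }
  pMan <- config$mangroveFraction * exp(-distShorePix / 45) *
    (1 + 1.3 * exp(-dMouthPix / 1500))
  cellIxOfPix <- matrix(((seq_len(npx) - 1L) %/% config$subres) + 1L, npx, npy)
  cellIyOfPix <- matrix(((seq_len(npy) - 1L) %/% config$subres) + 1L, npx, npy,
                        byrow = TRUE)
  pMan[developed[cbind(as.vector(cellIxOfPix), as.vector(cellIyOfPix))]] <-
    0.05 * pMan[developed[cbind(as.vector(cellIxOfPix), as.vector(cellIyOfPix))]]
  pMan <- clip(pMan, 0, 0.95)
  mangrove <- withSeed(childSeed(seed, 1L), {
    matrix(as.integer(stats::runif(npx * npy) < pMan), npx, npy)
  })

  # per-cell habitat covariates via the raster toolkit
  focal <- mangroveFocalSum(mangrove)
  mdts <- mangroveDistanceToShore(mangrove, shore, bufferM = 3 * ps,
                                  pixelSize = ps)
  zones <- matrix((cellIyOfPix - 1L) * nx + cellIxOfPix, npx, npy)
  zt <- zonalStats(distRaster = mdts, focalRaster = focal, zones = zones,
                   allZones = seq_len(nx * ny))
  cells <- data.frame(microgrid = seq_len(nx * ny),
                      ix = as.vector(ix), iy = as.vector(iy),
                      x = as.vector(X), y = as.vector(Y),
                      water = as.vector(water),
                      Min_Depth = as.vector(depth),
                      DistToRM = as.vector(distToRM),
                      River = as.vector(riverId),
                      DevelopedSL = as.integer(as.vector(developed)))
  cells$Sum_MNN <- zt$Sum_MNN[match(cells$microgrid, zt$zone)]
  cells$Min_MDTS <- zt$Min_MDTS[match(cells$microgrid, zt$zone)]

  new("EstuaryScene", cellSize = cs, nx = nx, ny = ny, cellX = cellX,
      cellY = cellY, water = water, depth = depth, riverId = riverId,
      distToRM = distToRM, developed = developed,
      distShoreCell = distShoreCell, shoreline = shore, riverMouths = mouths,
      mangroveMask = mangrove, distShorePix = distShorePix, pixelSize = ps,
      zonal = cells, epoch = as.Date(config$epoch), config = config,
      seed = as.integer(seed))
}
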