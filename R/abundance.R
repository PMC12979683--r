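# Posterior-simulation abundance estimation over the nearshore prediction
# grid, trend testing and seasonal summaries.

#' Build the nearshore prediction grid
#'
#' Clips the micro-grids to the sampling frame: water cells at most
#' `maxDepthM` deep (cells exactly at the boundary are kept) whose area
#' within `maxShoreDistM` of the shoreline is positive. The soak area of a
#' cell is that clipped water area in square yards, computed from the
#' sub-cell pixel lattice. Cells where a survey set ever occurred are
#' flagged `inUniverse` (the sampled domain).
#'
#' @param scene an [EstuaryScene-class].
#' @param survey optional survey table; its `microgrid` column defines the
#'   sampling universe (none flagged if omitted).
#' @param maxShoreDistM shoreline clip distance (m), default 61.
#' @param maxDepthM depth cutoff (m), default 3 (the gillnet's limit).
#' @return a [PredictionGrid-class].
#' @export
buildPredictionGrid <- function(scene, survey = NULL, maxShoreDistM = 61,
                                maxDepthM = 3) {
  cells <- scene@zonal
  sub <- scene@config$subres
  near <- scene@distShorePix <= maxShoreDistM
  cellIx <- ((row(near) - 1L) %/% sub) + 1L
  cellIy <- ((col(near) - 1L) %/% sub) + 1L
  zone <- (cellIy - 1L) * scene@nx + cellIx
  frac <- tapply(as.vector(near), as.vector(zone), mean)
  cells$areaFrac <- as.numeric(frac[as.character(cells$microgrid)])
  keep <- cells$water & cells$Min_Depth > 0 & cells$Min_Depth <= maxDepthM &
    cells$areaFrac > 0
  g <- cells[keep, , drop = FALSE]
  if (!nrow(g)) stop("prediction grid is empty")
  g$soakAreaYd2 <- g$areaFrac * scene@cellSize^2 * M2YD^2
  g$inUniverse <- if (is.null(survey)) FALSE else
    g$microgrid %in% unique(survey$microgrid)
  rownames(g) <- NULL
  new("PredictionGrid", cells = g, maxShoreDistM = maxShoreDistM,
      maxDepthM = maxDepthM)
}

# nearest positive-definite repair by eigenvalue clipping
nearestPD <- function(V) {
  e <- eigen((V + t(V)) / 2, symmetric = TRUE)
  lam <- pmax(e$values, max(e$values) * 1e-10)
  e$vectors %*% (lam * t(e$vectors))
}

#' Sample the posterior of the fitted coefficients
#'
#' Draws coefficient vectors from the fitted model's posterior. The default
#' sampler is \pkg{mgcv}'s Metropolis-Hastings sampler for the penalized
#' posterior (`gam.mh`); a Gaussian approximation `N(beta-hat, V-hat)` is
#' available as `sampler = "gaussian"`. A non-positive-definite coefficient
#' covariance is repaired to the nearest PD matrix with a message.
#' Deterministic given the seed.
#'
#' @param fitres a converged [FitResult-class].
#' @param n number of draws (default 1000).
#' @param seed integer seed.
#' @param sampler "mh" or "gaussian".
#' @param burn MH burn-in iterations.
#' @param thin MH thinning interval.
#' @return matrix `[n, n_coef]` of coefficient draws, with attribute
#'   `sampler`.
#' @export
samplePosterior <- function(fitres, n = 1000, seed = 1L,
                            sampler = c("mh", "gaussian"), burn = 500,
                            thin = 2) {
  sampler <- match.arg(sampler)
  stopifnot(is(fitres, "FitResult"), fitres@converged)
  fit <- fitres@fit
  draws <- withSeed(childSeed(seed, 6L), {
    if (sampler == "mh") {
      bs <- utils::capture.output(
        res <- mgcv::gam.mh(fit, ns = n * thin, burn = burn, thin = thin))
      res$bs[seq_len(n), , drop = FALSE]
    } else {
      V <- fit$Vp
      ch <- tryCatch(chol(V), error = function(e) NULL)
      if (is.null(ch)) {
        message("coefficient covariance was not positive definite; ",
                "nearest-PD repair applied")
        V <- nearestPD(V)
      }
      MASS::mvrnorm(n, mu = stats::coef(fit), Sigma = V)
    }
  })
  attr(draws, "sampler") <- sampler
  draws
}

#' Estimate abundance over the prediction grid from posterior draws
#'
#' For every posterior coefficient draw, year and season, total abundance
#' is the sum over prediction-grid cells of
#' `soakAreaYd2 * refSoakMinutes * exp(eta)`, where `eta` uses the cell's
#' static habitat covariates and its season-averaged daily environmental
#' fields — i.e. the expected catch if every cell were swept for one
#' standard soak at catchability 1. Totals are computed for the sampled
#' domain and the full grid from the same draws (paired). Within each
#' year-season-domain stratum, draws exceeding `trimFactor` times the
#' stratum median (density projections into poorly sampled parameter
#' space) are masked before any summary; `trimFactor = Inf` retains
#' everything.
#'
#' @param draws coefficient matrix from [samplePosterior()] (or any matrix
#'   conformable with the model's prediction matrix).
#' @param fitres the [FitResult-class] the draws belong to.
#' @param grid a [PredictionGrid-class].
#' @param env the [EnvFieldSeries-class] supplying daily fields.
#' @param years years to predict.
#' @param seasons season labels to predict.
#' @param refSoakMinutes reference soak duration (min) scaling areas to
#'   yard-minutes.
#' @param trimFactor extreme-value trimming threshold (default 100).
#' @param envStride day step when averaging daily fields within a season.
#' @return an [AbundanceDraws-class].
#' @export
estimateAbundance <- function(draws, fitres, grid, env,
                              years = NULL,
                              seasons = c("Spring/Summer", "Fall/Winter"),
                              refSoakMinutes = 60, trimFactor = 100,
                              envStride = 15) {
  stopifnot(is(fitres, "FitResult"), fitres@converged,
            is(grid, "PredictionGrid"))
  g <- grid@cells
  if (is.null(years))
    years <- sort(unique(as.integer(strftime(env@dates, "%Y"))))
  years <- as.integer(years)
  domains <- c("sampled", "full")
  nd <- nrow(draws)
  arr <- array(NA_real_, dim = c(nd, length(years), length(seasons),
                                 length(domains)),
               dimnames = list(NULL, years, seasons, domains))
  idxMat <- cbind(g$ix, g$iy)
  w <- g$soakAreaYd2 * refSoakMinutes
  for (yi in seq_along(years)) for (si in seq_along(seasons)) {
    dts <- seasonDates(years[yi], seasons[si], env)
    if (!length(dts)) next
    em <- envMeanAtCells(env, dts[seq(1, length(dts), by = envStride)],
                         idxMat)
    nd2 <- cbind(em, g[c("Min_Depth", "Sum_MNN", "Min_MDTS", "DistToRM",
                         "River", "DevelopedSL")],
                 Year = years[yi], Season = seasons[si])
    nd2 <- canonicalFactors(nd2)
    nd2$effort <- 1
    Xp <- mgcv::predict.gam(fitres@fit, newdata = nd2, type = "lpmatrix")
    eta <- Xp %*% t(draws)                      # cells x draws
    dens <- exp(eta)
    arr[, yi, si, "full"] <- as.numeric(crossprod(dens, w))
    arr[, yi, si, "sampled"] <- as.numeric(crossprod(dens[g$inUniverse, ,
                                                          drop = FALSE],
                                                     w[g$inUniverse]))
  }
  retained <- array(TRUE, dim = dim(arr), dimnames = dimnames(arr))
  retained[is.na(arr)] <- FALSE
  if (is.finite(trimFactor)) {
    for (yi in seq_along(years)) for (si in seq_along(seasons))
      for (di in seq_along(domains)) {
        v <- arr[, yi, si, di]
        if (all(is.na(v))) next
        med <- stats::median(v, na.rm = TRUE)
        retained[, yi, si, di] <- !is.na(v) & v <= trimFactor * med
      }
  }
  if (!any(retained)) stop("all draws trimmed: degenerate fit")
  new("AbundanceDraws", draws = arr, retained = retained,
      years = years, seasons = seasons, domains = domains,
      trimFactor = trimFactor,
      meta = list(sampler = attr(draws, "sampler") %||% "external",
                  nDraws = nd, refSoakMinutes = refSoakMinutes,
                  envStride = envStride))
}

# dates belonging to one season of one year
seasonDates <- function(year, season, env) {
  if (season == "Spring/Summer") {
    dts <- seq(as.Date(sprintf("%d-03-01", year)),
               as.Date(sprintf("%d-08-31", year)), by = "day")
  } else {
    dts <- c(seq(as.Date(sprintf("%d-01-01", year)),
                 as.Date(sprintf("%d-02-28", year)), by = "day"),
             seq(as.Date(sprintf("%d-09-01", year)),
                 as.Date(sprintf("%d-12-31", year)), by = "day"))
  }
  dts[dts >= min(env@dates) & dts <= max(env@dates)]
}

#' Summarize abundance draws
#'
#' Median, mean, SD and range of retained draws per year x season x domain.
#'
#' @param object an [AbundanceDraws-class].
#' @return data.frame with year, season, domain, nRetained, median, mean,
#'   sd, min, max.
#' @export
summarizeAbundance <- function(object) {
  stopifnot(is(object, "AbundanceDraws"))
  rows <- list()
  for (y in object@years) for (s in object@seasons)
    for (dom in object@domains) {
      v <- object@draws[, as.character(y), s, dom]
      v <- v[object@retained[, as.character(y), s, dom]]
      rows[[length(rows) + 1L]] <- data.frame(
        year = y, season = s, domain = dom, nRetained = length(v),
        median = if (length(v)) stats::median(v) else NA_real_,
        mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) > 1) stats::sd(v) else NA_real_,
        min = if (length(v)) min(v) else NA_real_,
        max = if (length(v)) max(v) else NA_real_)
    }
  do.call(rbind, rows)
}

#' Pairwise interannual comparison of predicted abundance
#'
#' One-way ANOVA of draw-level totals across years followed by Tukey HSD
#' pairwise comparisons, reported as a compact letter display (years
#' sharing a letter are not significantly different).
#'
#' @param object an [AbundanceDraws-class].
#' @param season,domain the stratum to compare.
#' @param alpha significance level for the letter display.
#' @return list with `letters` (data.frame year, median, letters), `anova`
#'   (the aov fit) and `tukey` (the glht summary), the latter two NULL for
#'   a single year.
#' @export
compareYears <- function(object, season = "Spring/Summer",
                         domain = "sampled", alpha = 0.05) {
  stopifnot(is(object, "AbundanceDraws"))
  rows <- list()
  for (y in object@years) {
    v <- object@draws[, as.character(y), season, domain]
    keep <- object@retained[, as.character(y), season, domain]
    if (sum(keep) >= 2L)
      rows[[as.character(y)]] <- data.frame(year = y, total = v[keep])
  }
  d <- do.call(rbind, rows)
  meds <- stats::aggregate(total ~ year, d, stats::median)
  if (length(unique(d$year)) < 2L) {
    return(list(letters = data.frame(year = meds$year, median = meds$total,
                                     letters = "a"),
                anova = NULL, tukey = NULL))
  }
  d$year <- factor(d$year)
  fit <- stats::aov(total ~ year, data = d)
  glt <- multcomp::glht(fit, linfct = multcomp::mcp(year = "Tukey"))
  # multivariate-t completion warnings from the adjusted p-values are benign
  cld <- suppressWarnings(multcomp::cld(glt, level = alpha))
  lets <- cld$mcletters$Letters
  list(letters = data.frame(year = as.integer(names(lets)),
                            median = meds$total[match(names(lets),
                                                      meds$year)],
                            letters = unname(lets)),
       anova = fit, tukey = suppressWarnings(summary(glt)))
}

#' Interannual change ratios
#'
#' Ratios of successive yearly abundance values `N[t+1] / N[t]` with their
#' mean, SD and range. Accepts a named numeric vector of yearly medians or
#' an [AbundanceDraws-class] (whose retained-draw medians are used).
#'
#' @param x named numeric (names = years) or [AbundanceDraws-class].
#' @param season,domain stratum used when `x` is an
#'   [AbundanceDraws-class].
#' @return list with `ratios` (named by transition), `mean`, `sd`,
#'   `range`.
#' @export
interannualChange <- function(x, season = "Spring/Summer",
                              domain = "sampled") {
  if (is(x, "AbundanceDraws")) {
    s <- summarizeAbundance(x)
    s <- s[s$season == season & s$domain == domain, ]
    x <- stats::setNames(s$median, s$year)
  }
  if (length(x) < 2L) stop("need at least 2 years")
  if (any(x == 0)) stop("zero yearly abundance: ratios undefined")
  r <- x[-1] / x[-length(x)]
  names(r) <- paste(names(x)[-length(x)], names(x)[-1], sep = "->")
  list(ratios = r, mean = mean(r), sd = stats::sd(r), range = range(r))
}
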