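#' Generate a daily environmental field series
#'
#' Sets up daily per-cell water temperature (deg C), dissolved oxygen
#' (mg/L), salinity and pH surfaces over a scene. Each surface is the sum
#' of a deterministic component — a sinusoidal seasonal cycle plus, for
#' salinity, a logistic upriver freshening gradient in distance to the
#' river mouth — and spatially smooth random day-to-day variation built
#' from low-frequency spatial basis functions with independent daily
#' coefficients. Values are clipped to physical envelopes whose defaults
#' are the observed ranges in the study system (temperature 14.7-35.8 deg C,
#' DO 0.4-11.9 mg/L, salinity 0.1-35.9).
#'
#' Fields are recomputed deterministically from (seed, date) by
#' [envField()], so the object is light regardless of the date span.
#'
#' @param scene an [EstuaryScene-class].
#' @param dates Date vector (a range; all days in `range(dates)` are
#'   available). Must not precede the scene epoch.
#' @param seed integer seed.
#' @param noiseAmp named amplitudes of the smooth random fields; 0 gives
#'   the deterministic mean surface exactly.
#' @param envelopes named list of c(lo, hi) clipping ranges.
#' @return an [EnvFieldSeries-class].
#' @export
generateEnvironment <- function(scene, dates, seed = 1L,
                                noiseAmp = c(temp = 1.1, do = 0.7,
                                             salin = 1.8, ph = 0.12),
                                envelopes = list(temp = c(14.7, 35.8),
                                                 do = c(0.4, 11.9),
                                                 salin = c(0.1, 35.9),
                                                 ph = c(6.8, 8.8))) {
  dates <- as.Date(dates)
  if (!length(dates)) stop("'dates' must be nonempty")
  if (min(dates) < scene@epoch)
    stop("date range starts before the scene epoch (", scene@epoch, ")")
  params <- list(tempMean = 25.25, tempAmp = 9.0, tempPeakDoy = 197,
                 tempUpriver = 0.5, salSea = 33, salRange = 30,
                 salScale = 700, salSeasAmp = 2.5, salSeasDoy = 60,
                 doBase = 7.2, doTempSlope = -0.13, phBase = 7.9,
                 phSeasAmp = 0.1)
  new("EnvFieldSeries", scene = scene,
      dates = seq(min(dates), max(dates), by = "day"),
      seed = as.integer(seed), noiseAmp = noiseAmp, envelopes = envelopes,
      params = params)
}

# smooth spatial basis functions used for correlated day-to-day variation
envNoiseBasis <- function(scene) {
  nx <- scene@nx; ny <- scene@ny
  u <- matrix(scene@cellX[row(scene@water)] / (nx * scene@cellSize), nx, ny)
  v <- matrix(scene@cellY[col(scene@water)] / (ny * scene@cellSize), nx, ny)
  list(cos(pi * u), cos(pi * v), sin(pi * u) * cos(pi * v),
       cos(2 * pi * u) * sin(pi * v))
}

#' Evaluate daily environmental fields
#'
#' Computes the temperature, DO, salinity and pH surfaces of an
#' [EnvFieldSeries-class] on one day. Deterministic given the series seed
#' and the date. Land cells are `NA`.
#'
#' @param env an [EnvFieldSeries-class].
#' @param date a Date within the series range.
#' @return named list of matrices `temp`, `do`, `salin`, `ph`.
#' @export
envField <- function(env, date) {
  date <- as.Date(date)
  if (date < min(env@dates) || date > max(env@dates))
    stop("date outside the series range")
  sc <- env@scene
  p <- env@params
  doy <- as.integer(strftime(date, "%j"))
  seas <- function(amp, peak) -amp * cos(2 * pi * (doy - peak) / 365.25)
  dRM <- sc@distToRM

  tempM <- p$tempMean + seas(-p$tempAmp, p$tempPeakDoy) +
    p$tempUpriver * tanh(dRM / 2000)
  salM <- p$salSea - p$salRange * stats::plogis(dRM / p$salScale) +
    seas(p$salSeasAmp, p$salSeasDoy)
  doM <- p$doBase + p$doTempSlope * (tempM - 25)
  phM <- p$phBase + seas(p$phSeasAmp, p$salSeasDoy)

  dayIdx <- as.integer(date - sc@epoch)
  basis <- envNoiseBasis(sc)
  flds <- list(temp = tempM, do = doM, salin = salM, ph = phM)
  amps <- env@noiseAmp
  withSeed(childSeed(env@seed, dayIdx), {
    for (nm in names(flds)) {
      a <- amps[[nm]] %||% 0
      if (is.na(a)) a <- 0
      if (a > 0) {
        co <- stats::rnorm(length(basis) + 1L, 0, a)
        noise <- co[1] / 2
        for (k in seq_along(basis)) noise <- noise + co[k + 1L] * basis[[k]]
        flds[[nm]] <- flds[[nm]] + noise
      } else {
        stats::rnorm(length(basis) + 1L)  # keep the stream aligned
      }
    }
  })
  for (nm in names(flds)) {
    e <- env@envelopes[[nm]]
    flds[[nm]] <- clip(flds[[nm]], e[1], e[2])
    flds[[nm]][!sc@water] <- NA_real_
  }
  flds
}

# mean environmental fields at a set of cells over a set of dates
envMeanAtCells <- function(env, dates, cellIdx) {
  acc <- NULL
  for (d in as.list(dates)) {
    f <- envField(env, d)
    row <- cbind(Avg_temp = f$temp[cellIdx], Avg_DO = f$do[cellIdx],
                 Avg_salin = f$salin[cellIdx], Avg_pH = f$ph[cellIdx])
    acc <- if (is.null(acc)) row else acc + row
  }
  as.data.frame(acc / length(dates))
}
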