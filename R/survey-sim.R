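#' Construct a random gillnet survey design
#'
#' Defaults mirror a long-term fishery-independent survey: 16 sets per
#' month split across the three river regions on two trip dates per month,
#' 61-m nets (occasionally 30.5-m in confined habitat) of 2.5-m height
#' soaked for one hour, over 2010-2022. With the default scene this yields
#' about 2500 sets over the series.
#'
#' @param setsPerMonth named numeric: sets per month per region (A/B/C).
#' @param tripsPerMonth sampling trips per region per month.
#' @param netLengthsM c(short, long) net lengths in metres.
#' @param probShortNet probability of using the short net for a set.
#' @param netHeightM net height in metres (configurable; the field protocol
#'   fixes only length and mesh).
#' @param soakMinutes soak duration, minutes.
#' @param years calendar years covered.
#' @return a [SurveyDesign-class].
#' @export
surveyDesign <- function(setsPerMonth = c(A = 6, B = 5, C = 5),
                         tripsPerMonth = 2L,
                         netLengthsM = c(30.5, 61), probShortNet = 0.15,
                         netHeightM = 2.5, soakMinutes = 60,
                         years = 2010:2022) {
  new("SurveyDesign", setsPerMonth = setsPerMonth,
      tripsPerMonth = as.integer(tripsPerMonth), netLengthsM = netLengthsM,
      probShortNet = probShortNet, netHeightM = netHeightM,
      soakMinutes = soakMinutes, years = as.integer(years))
}

# random juvenile lengths/sexes for a catch of n fish
sampleFish <- function(n) {
  if (n == 0L) return(list(stl = numeric(0), sex = character(0)))
  age0 <- stats::runif(n) < 0.6
  stl <- ifelse(age0, stats::runif(n, 0.68, 1.33), stats::runif(n, 1.40, 1.86))
  list(stl = round(stl, 2), sex = sample(c("M", "F"), n, replace = TRUE))
}

#' Simulate a random gillnet survey
#'
#' Places sets by stratified random draws of micro-grid cells (water,
#' depth <= 3 m, within the region) per region per month on random trip
#' dates, assembles per-set covariates from the scene and the daily
#' environmental fields (with optional sonde observation noise), computes
#' yard-minute effort from the net dimensions and soak time, and draws
#' catches as exact Tweedie (compound Poisson-gamma) counts with mean
#' `effort * exp(eta)` where `eta` is the true linear predictor.
#'
#' @param scene an [EstuaryScene-class].
#' @param env an [EnvFieldSeries-class] covering the survey years.
#' @param trueModel a [TrueModel-class].
#' @param design a [SurveyDesign-class].
#' @param seed integer seed; the survey is deterministic given its inputs.
#' @param envObsSd sd of sonde observation noise added to the recorded
#'   (not the generating) covariate values.
#' @return data.frame of survey sets with canonical covariate columns
#'   (Min_Depth, Avg_temp, Avg_DO, Avg_salin, Avg_pH, Sum_MNN, Min_MDTS,
#'   Year, Season, River, DistToRM, DevelopedSL), effort in yard-minutes,
#'   integer `nCaught`, and per-fish `lengthsSTL` / `sexes`
#'   (semicolon-separated).
#' @export
simulateSurvey <- function(scene, env, trueModel = defaultTrueModel(),
                           design = surveyDesign(), seed = 1L,
                           envObsSd = 0.1) {
  cells <- scene@zonal
  eligible <- split(which(cells$water & cells$Min_Depth <= 3 &
                            cells$Min_Depth > 0),
                    cells$River[cells$water & cells$Min_Depth <= 3 &
                                  cells$Min_Depth > 0])
  sets <- withSeed(childSeed(seed, 2L), {
    rows <- list()
    for (year in design@years) for (month in 1:12) {
      first <- as.Date(sprintf("%d-%02d-01", year, month))
      nDays <- as.integer(strftime(seq(first, by = "month",
                                       length.out = 2)[2] - 1, "%d"))
      for (region in names(design@setsPerMonth)) {
        k <- design@setsPerMonth[[region]]
        if (k <= 0) next
        pool <- eligible[[region]]
        if (is.null(pool) || !length(pool)) next
        tripDays <- sort(sample.int(nDays, min(design@tripsPerMonth, nDays)))
        picked <- sample(pool, min(k, length(pool)))
        for (j in seq_along(picked)) {
          day <- tripDays[1L + (j - 1L) %% length(tripDays)]
          len <- if (stats::runif(1) < design@probShortNet)
            min(design@netLengthsM) else max(design@netLengthsM)
          rows[[length(rows) + 1L]] <- data.frame(
            cell = picked[j], date = as.Date(sprintf("%d-%02d-%02d",
                                                     year, month, day)),
            netLengthM = len)
        }
      }
    }
    do.call(rbind, rows)
  })
  n <- nrow(sets)
  areaYd2 <- (sets$netLengthM * M2YD) * (design@netHeightM * M2YD)
  effort <- design@soakMinutes * areaYd2
  ci <- sets$cell
  out <- data.frame(setId = sprintf("S%05d", seq_len(n)), date = sets$date,
                    x = cells$x[ci], y = cells$y[ci], microgrid = ci,
                    effort = effort, netLengthM = sets$netLengthM,
                    Min_Depth = cells$Min_Depth[ci],
                    Sum_MNN = cells$Sum_MNN[ci],
                    Min_MDTS = cells$Min_MDTS[ci],
                    Year = as.integer(strftime(sets$date, "%Y")),
                    Season = as.character(assignSeason(sets$date)),
                    River = cells$River[ci], DistToRM = cells$DistToRM[ci],
                    DevelopedSL = cells$DevelopedSL[ci],
                    stringsAsFactors = FALSE)
  # true daily field values per set (grouped by date), then recorded values
  truth <- matrix(NA_real_, n, 4,
                  dimnames = list(NULL, c("Avg_temp", "Avg_DO", "Avg_salin",
                                          "Avg_pH")))
  idxMat <- cbind(cells$ix[ci], cells$iy[ci])
  for (d in split(seq_len(n), as.character(sets$date))) {
    f <- envField(env, out$date[d[1]])
    truth[d, ] <- cbind(f$temp[idxMat[d, , drop = FALSE]],
                        f$do[idxMat[d, , drop = FALSE]],
                        f$salin[idxMat[d, , drop = FALSE]],
                        f$ph[idxMat[d, , drop = FALSE]])
  }
  etaDat <- cbind(out, as.data.frame(truth))
  eta <- trueLinearPredictor(trueModel, etaDat)
  mu <- effort * exp(eta)
  if (any(!is.finite(mu))) stop("non-finite expected catch")
  catches <- withSeed(childSeed(seed, 3L), {
    y <- rtweedie(n, mu = mu, p = trueModel@p, phi = trueModel@phi)
    nc <- as.integer(roundHalfUp(y))
    fish <- lapply(nc, sampleFish)
    obs <- truth + matrix(stats::rnorm(4 * n, 0, envObsSd), n, 4)
    list(nCaught = nc, fish = fish, obs = obs)
  })
  obs <- catches$obs
  out$Avg_temp <- obs[, "Avg_temp"]; out$Avg_DO <- obs[, "Avg_DO"]
  out$Avg_salin <- obs[, "Avg_salin"]; out$Avg_pH <- obs[, "Avg_pH"]
  out$nCaught <- catches$nCaught
  out$lengthsSTL <- vapply(catches$fish, function(f)
    paste(f$stl, collapse = ";"), character(1))
  out$sexes <- vapply(catches$fish, function(f)
    paste(f$sex, collapse = ";"), character(1))
  attr(out, "trueEta") <- eta
  out
}

#' Simulate independent sightings
#'
#' Draws `n` point-date sighting records over cells with depth <= 3 m,
#' with per-day cell probabilities proportional to the true density
#' `exp(eta)` (uniform over valid cells when all effects are constant).
#'
#' @param scene an [EstuaryScene-class].
#' @param env an [EnvFieldSeries-class].
#' @param trueModel a [TrueModel-class].
#' @param n number of sightings, >= 1.
#' @param seed integer seed.
#' @param dates optional Date vector to draw sighting dates from (defaults
#'   to the whole series range).
#' @return data.frame with sightingId, date, microgrid, x, y.
#' @export
simulateSightings <- function(scene, env, trueModel, n, seed = 1L,
                              dates = NULL) {
  if (n < 1L) stop("'n' must be >= 1")
  cells <- scene@zonal
  valid <- which(cells$water & cells$Min_Depth <= 3 & cells$Min_Depth > 0)
  if (!length(valid)) stop("no valid cells with depth <= 3 m")
  if (is.null(dates)) dates <- env@dates
  idxMat <- cbind(cells$ix[valid], cells$iy[valid])
  withSeed(childSeed(seed, 4L), {
    dts <- sample(dates, n, replace = TRUE)
    chosen <- integer(n)
    for (d in split(seq_len(n), as.character(dts))) {
      f <- envField(env, dts[d[1]])
      cov <- data.frame(Avg_temp = f$temp[idxMat], Avg_DO = f$do[idxMat],
                        Avg_salin = f$salin[idxMat],
                        Sum_MNN = cells$Sum_MNN[valid],
                        Year = as.integer(strftime(dts[d[1]], "%Y")),
                        DistToRM = cells$DistToRM[valid],
                        DevelopedSL = cells$DevelopedSL[valid])
      w <- exp(trueLinearPredictor(trueModel, cov))
      chosen[d] <- sample(valid, length(d), replace = TRUE, prob = w)
    }
    data.frame(sightingId = sprintf("X%05d", seq_len(n)), date = dts,
               microgrid = chosen, x = cells$x[chosen], y = cells$y[chosen])
  })
}
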