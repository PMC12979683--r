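# Survey-table preparation: effort, season and age rules, CPUE, and the
# environmental interpolator.

#' Gillnet effort in yard-minutes
#'
#' Effort = soak duration in minutes times net area in square yards
#' (length x height, metres converted at 1 m = 1.0936133 yd).
#'
#' @param startTime,endTime POSIXct set start and end; end must be after
#'   start. Alternatively pass `minutes` directly.
#' @param netLengthM,netHeightM net dimensions in metres.
#' @param minutes soak duration in minutes (overrides the time pair).
#' @return effort in yard-minutes.
#' @examples
#' computeEffort(minutes = 60, netLengthM = 61, netHeightM = 2.5)
#' @export
computeEffort <- function(startTime = NULL, endTime = NULL, netLengthM,
                          netHeightM, minutes = NULL) {
  if (is.null(minutes)) {
    minutes <- as.numeric(difftime(endTime, startTime, units = "mins"))
  }
  if (any(minutes <= 0)) stop("soak duration must be positive")
  if (any(netLengthM <= 0) || any(netHeightM <= 0))
    stop("net dimensions must be positive")
  minutes * (netLengthM * M2YD) * (netHeightM * M2YD)
}

#' Assign season from date
#'
#' March through August is "Spring/Summer"; all other months are
#' "Fall/Winter".
#'
#' @param date Date vector.
#' @return factor with levels Fall/Winter, Spring/Summer.
#' @export
assignSeason <- function(date) {
  m <- as.integer(strftime(as.Date(date), "%m"))
  factor(ifelse(m >= 3L & m <= 8L, "Spring/Summer", "Fall/Winter"),
         levels = c("Fall/Winter", "Spring/Summer"))
}

#' Filter catches to small juveniles
#'
#' Keeps fish of 1.86 m STL or less (inclusive), approximating the age-0
#' and age-1 year classes. Records with missing STL are excluded with a
#' warning.
#'
#' @param fish data.frame with a numeric `stl` column (metres).
#' @param maxSTL inclusive length cutoff (m).
#' @return the juvenile subset of `fish`.
#' @export
filterJuveniles <- function(fish, maxSTL = 1.86) {
  miss <- is.na(fish$stl)
  if (any(miss))
    warning(sum(miss), " record(s) with missing STL excluded")
  fish[!miss & fish$stl <= maxSTL, , drop = FALSE]
}

#' Assign age class from length and sex
#'
#' Males under 1.34 m and females under 1.38 m are age-0 (strict
#' inequalities); anything above 1.86 m is older than age-1; the remainder
#' is age-1. Fish of unknown sex use a configurable midpoint cutoff
#' (default 1.36 m) and are reported via a message.
#'
#' @param stl STL in metres, > 0.
#' @param sex "M", "F", or anything else for unknown.
#' @param unknownCutoff age-0 cutoff applied to unknown-sex fish.
#' @return character vector in {"age0", "age1", "older"}.
#' @export
assignAgeClass <- function(stl, sex, unknownCutoff = 1.36) {
  if (any(stl <= 0, na.rm = TRUE)) stop("STL must be > 0")
  sex <- as.character(sex)
  unk <- !(sex %in% c("M", "F"))
  if (any(unk))
    message(sum(unk), " fish of unknown sex aged with the ",
            unknownCutoff, " m midpoint rule")
  cut0 <- ifelse(sex == "M", 1.34, ifelse(sex == "F", 1.38, unknownCutoff))
  ifelse(stl > 1.86, "older", ifelse(stl < cut0, "age0", "age1"))
}

#' Catch per unit effort
#'
#' CPUE per group as total catch over total effort, scaled to catch per
#' 10^6 yard-minutes. Groups present in the effort table but absent from
#' the catch table get CPUE 0 (zero catch over recorded effort).
#'
#' @param catch data.frame with grouping columns and a count column `n`.
#' @param effort data.frame with the same grouping columns and an `effort`
#'   column (yard-minutes); group effort totals must be positive.
#' @param by character vector of grouping column names.
#' @return data.frame of groups with columns n, effort, cpue.
#' @export
cpue <- function(catch, effort, by) {
  eff <- stats::aggregate(effort["effort"], effort[by], sum)
  if (any(eff$effort <= 0)) stop("group effort totals must be positive")
  ct <- if (nrow(catch)) stats::aggregate(catch["n"], catch[by], sum) else NULL
  out <- eff
  out$n <- 0
  if (!is.null(ct)) {
    key <- function(d) do.call(paste, c(d[by], sep = "\r"))
    m <- match(key(out), key(ct))
    out$n[!is.na(m)] <- ct$n[m[!is.na(m)]]
  }
  out$cpue <- out$n / out$effort * 1e6
  out[do.call(order, out[by]), c(by, "n", "effort", "cpue")]
}

#' Juvenile CPUE by age class and year from a simulated survey table
#'
#' Expands per-fish length/sex records, ages them with [assignAgeClass()],
#' and reports catch per 10^6 yard-minutes by Year x age class.
#'
#' @param survey a survey table from [simulateSurvey()].
#' @return data.frame with Year, ageClass, n, effort, cpue.
#' @export
cpueByAge <- function(survey) {
  fish <- do.call(rbind, lapply(which(survey$nCaught > 0), function(i) {
    stl <- as.numeric(strsplit(survey$lengthsSTL[i], ";")[[1]])
    sex <- strsplit(survey$sexes[i], ";")[[1]]
    data.frame(Year = survey$Year[i], stl = stl, sex = sex)
  }))
  eff <- survey[c("Year", "effort")]
  ages <- c("age0", "age1")
  out <- do.call(rbind, lapply(ages, function(a) {
    ct <- if (!is.null(fish) && nrow(fish)) {
      f <- fish[assignAgeClass(fish$stl, fish$sex) == a, , drop = FALSE]
      data.frame(Year = f$Year, n = rep(1, nrow(f)))
    } else data.frame(Year = integer(0), n = numeric(0))
    z <- cpue(ct, eff, by = "Year")
    z$ageClass <- a
    z
  }))
  out[order(out$Year, out$ageClass), ]
}

#' Interpolate point environmental observations onto the scene grid
#'
#' Builds smooth per-cell daily fields from scattered sonde observations by
#' ordinary kriging with an exponential variogram (inverse-distance
#' weighting available as a fallback). Sub-daily repeats at a location
#' should be pre-averaged per location per day; this function averages any
#' exact duplicates defensively. With a zero nugget the interpolator is
#' exact at observation cells. Days with fewer than 3 points fall back to
#' the mean field of all observations in the same season, with a warning.
#'
#' @param obs data.frame with columns date, x, y, value.
#' @param scene an [EstuaryScene-class].
#' @param method "kriging" or "idw".
#' @param range exponential variogram range (m); default one quarter of the
#'   domain diagonal.
#' @param nugget variogram nugget (same units as the data variance).
#' @param idwPower inverse-distance power for the fallback method.
#' @return named list (by date, ISO-8601) of per-cell matrices (`NA` on
#'   land).
#' @export
interpolateEnvironment <- function(obs, scene, method = c("kriging", "idw"),
                                   range = NULL, nugget = 0, idwPower = 2) {
  method <- match.arg(method)
  obs$date <- as.Date(obs$date)
  # average duplicates per location per day
  obs <- stats::aggregate(value ~ date + x + y, data = obs, FUN = mean)
  if (is.null(range))
    range <- 0.25 * sqrt((scene@nx * scene@cellSize)^2 +
                           (scene@ny * scene@cellSize)^2)
  X <- matrix(scene@cellX[row(scene@water)], scene@nx, scene@ny)
  Y <- matrix(scene@cellY[col(scene@water)], scene@nx, scene@ny)
  tx <- as.vector(X); ty <- as.vector(Y)
  out <- list()
  for (d in sort(unique(obs$date))) {
    o <- obs[obs$date == d, , drop = FALSE]
    if (nrow(o) < 3L) {
      warning("day ", as.Date(d), " has < 3 observations; ",
              "season-mean fallback used")
      seas <- assignSeason(d)
      pool <- obs[assignSeason(obs$date) == seas, , drop = FALSE]
      fld <- matrix(mean(pool$value), scene@nx, scene@ny)
    } else if (method == "idw") {
      w <- 1 / outer(seq_along(tx), seq_len(nrow(o)), function(i, j)
        pmax(sqrt((tx[i] - o$x[j])^2 + (ty[i] - o$y[j])^2), 1e-9))^idwPower
      fld <- matrix(as.vector(w %*% o$value) / rowSums(w),
                    scene@nx, scene@ny)
    } else {
      n <- nrow(o)
      sill <- max(stats::var(o$value), 1e-10) + nugget
      gam <- function(h) nugget * (h > 0) + (sill - nugget) *
        (1 - exp(-h / range))
      Dobs <- as.matrix(stats::dist(cbind(o$x, o$y)))
      K <- rbind(cbind(-gam(Dobs), 1), c(rep(1, n), 0))
      Dt <- outer(seq_along(tx), seq_len(n), function(i, j)
        sqrt((tx[i] - o$x[j])^2 + (ty[i] - o$y[j])^2))
      k <- rbind(t(-gam(Dt)), 1)
      wts <- solve(K, k)
      fld <- matrix(as.vector(crossprod(wts[seq_len(n), , drop = FALSE],
                                        o$value)), scene@nx, scene@ny)
    }
    fld[!scene@water] <- NA_real_
    out[[as.character(as.Date(d))]] <- fld
  }
  out
}
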