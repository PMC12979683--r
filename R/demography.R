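# Back-calculation of adult-female abundance from juvenile abundance via
# the brood-size and stable-age-distribution approaches.

#' Construct a demography configuration
#'
#' Defaults are the published life-history reconstruction for this
#' population: broods of 7-14 pups on a biennial female cycle, a 50% female
#' fraction, a truncated normal for combined age-0 + age-1 female abundance
#' (mu 251.481, sigma 81.41511, truncated to [178.511, 504.7369] — note
#' that doubling these gives the juvenile abundance summaries 503 / 357 /
#' 1009 after rounding), and a uniform integer maturity age on [7, 11].
#' Stable-age ratios are supplied externally (see [syntheticStableAge()]
#' for a labelled synthetic stand-in).
#'
#' @param broodMin,broodMax pups per brood.
#' @param reproCycleYears years between broods for one female.
#' @param femaleFraction fraction of juveniles that are female.
#' @param tnMean,tnSD,tnA,tnB truncated-normal parameters for juvenile
#'   females.
#' @param maturityMin,maturityMax integer bounds of age at maturity.
#' @param stableAgeRatios named numeric of stable-age proportions by age
#'   (must sum to 1); may be omitted for the brood-size approach.
#' @param nRealizations Monte Carlo realizations.
#' @return a [DemographyConfig-class].
#' @export
demographyConfig <- function(broodMin = 7, broodMax = 14,
                             reproCycleYears = 2, femaleFraction = 0.5,
                             tnMean = 251.481, tnSD = 81.41511,
                             tnA = 178.511, tnB = 504.7369,
                             maturityMin = 7L, maturityMax = 11L,
                             stableAgeRatios = numeric(0),
                             nRealizations = 1000L) {
  new("DemographyConfig", broodMin = broodMin, broodMax = broodMax,
      reproCycleYears = reproCycleYears, femaleFraction = femaleFraction,
      tnMean = tnMean, tnSD = tnSD, tnA = tnA, tnB = tnB,
      maturityMin = as.integer(maturityMin),
      maturityMax = as.integer(maturityMax),
      stableAgeRatios = stableAgeRatios,
      nRealizations = as.integer(nRealizations))
}

#' Draw from a truncated normal distribution
#'
#' Inverse-CDF sampling of `N(mean, sd)` truncated to `[a, b]`; all draws
#' lie inside the bounds.
#'
#' @param n number of draws.
#' @param mean,sd normal parameters.
#' @param a,b truncation bounds, `a < b`.
#' @return numeric vector of draws in `[a, b]`.
#' @export
rtruncnorm <- function(n, mean = 0, sd = 1, a = -Inf, b = Inf) {
  if (a >= b) stop("'a' must be < 'b'")
  pa <- stats::pnorm((a - mean) / sd)
  pb <- stats::pnorm((b - mean) / sd)
  mean + sd * stats::qnorm(stats::runif(n, pa, pb))
}

# analytic mean of the truncated normal (used by tests as an oracle)
truncnormMean <- function(mean, sd, a, b) {
  al <- (a - mean) / sd; be <- (b - mean) / sd
  mean + sd * (stats::dnorm(al) - stats::dnorm(be)) /
    (stats::pnorm(be) - stats::pnorm(al))
}

#' Juvenile abundance summaries implied by the demography configuration
#'
#' Total (both-sex) juvenile abundance equals the truncated-normal female
#' draws divided by the female fraction; with the default 50% this doubles
#' the parameters, giving median `mu / fraction`, minimum `a / fraction`
#' and maximum `b / fraction` (503, 357 and 1009 rounded, under the
#' defaults).
#'
#' @param config a [DemographyConfig-class].
#' @return list with `median`, `min`, `max` and their `rounded` versions.
#' @export
juvenileAbundanceSummary <- function(config) {
  f <- config@femaleFraction
  out <- list(median = config@tnMean / f, min = config@tnA / f,
              max = config@tnB / f)
  out$rounded <- lapply(out, roundHalfUp)
  out
}

#' Back-calculate adult females from brood size
#'
#' Divides juvenile abundance by expected brood size (one brood per female
#' per reproductive cycle, with the biennial cycle already embodied in
#' dividing the standing two-cohort abundance by a single brood).
#'
#' Two modes: `summary` reproduces the arithmetic of a point estimate with
#' a range — point = median juvenile abundance / midpoint brood size,
#' range = [min abundance / broodMax, max abundance / broodMin], each
#' rounded half away from zero; `mc` draws realizations
#' `J_k / B_k` with `J_k` juvenile totals (truncated-normal female draws
#' scaled by the female fraction) and `B_k` uniform brood sizes, and
#' reports their median, SD and range.
#'
#' @param juveniles either NULL (derive from the configuration's truncated
#'   normal), a list with `median`/`min`/`max` (summary mode), or a numeric
#'   vector of juvenile-abundance draws (mc mode).
#' @param config a [DemographyConfig-class].
#' @param mode "summary" or "mc".
#' @param seed Monte Carlo seed.
#' @param integerBrood draw integer-valued brood sizes in mc mode.
#' @return list with the mode's estimate, spread and range.
#' @export
broodsizeBackcalc <- function(juveniles = NULL, config = demographyConfig(),
                              mode = c("summary", "mc"), seed = 1L,
                              integerBrood = FALSE) {
  mode <- match.arg(mode)
  if (config@broodMin <= 0) stop("brood size must be positive")
  if (mode == "summary") {
    if (is.null(juveniles)) {
      js <- juvenileAbundanceSummary(config)
      juveniles <- list(median = js$median, min = js$min, max = js$max)
    }
    if (any(unlist(juveniles[c("median", "min", "max")]) <= 0))
      stop("juvenile abundance must be positive")
    mid <- (config@broodMin + config@broodMax) / 2
    list(mode = "summary",
         adultFemales = roundHalfUp(juveniles$median / mid),
         range = c(roundHalfUp(juveniles$min / config@broodMax),
                   roundHalfUp(juveniles$max / config@broodMin)),
         broodMidpoint = mid)
  } else {
    withSeed(childSeed(seed, 7L), {
      n <- config@nRealizations
      J <- if (is.numeric(juveniles) && length(juveniles) > 1L)
        sample(juveniles, n, replace = TRUE)
      else rtruncnorm(n, config@tnMean, config@tnSD, config@tnA,
                      config@tnB) / config@femaleFraction
      B <- if (integerBrood) {
        lo <- ceiling(config@broodMin)
        lo + sample.int(floor(config@broodMax) - lo + 1L, n,
                        replace = TRUE) - 1L
      } else stats::runif(n, config@broodMin, config@broodMax)
      A <- J / B
      list(mode = "mc", adultFemales = stats::median(A), sd = stats::sd(A),
           range = range(A), realizations = A)
    })
  }
}

#' Back-calculate adult females from a stable age distribution
#'
#' For each realization, draws the juvenile (age-0 + age-1) female
#' abundance from the truncated normal and a maturity threshold `m` from
#' the uniform integer distribution, then scales by the stable-age
#' distribution: adults = females x (sum of ratios at ages >= m) / (ratio
#' at age 0 + ratio at age 1). Reports the median, SD and range of the
#' realizations.
#'
#' @param config a [DemographyConfig-class] with `stableAgeRatios` set.
#' @param seed Monte Carlo seed.
#' @return list with adultFemales (median), sd, range, realizations.
#' @export
stableAgeBackcalc <- function(config, seed = 1L) {
  r <- config@stableAgeRatios
  if (!length(r)) stop("stable-age ratios are required")
  ages <- as.numeric(names(r))
  denom <- sum(r[ages %in% c(0, 1)])
  if (denom == 0) stop("stable-age mass at ages 0-1 is zero")
  withSeed(childSeed(seed, 8L), {
    n <- config@nRealizations
    F <- rtruncnorm(n, config@tnMean, config@tnSD, config@tnA, config@tnB)
    m <- config@maturityMin +
      sample.int(config@maturityMax - config@maturityMin + 1L, n,
                 replace = TRUE) - 1L
    adultFrac <- vapply(m, function(mm) sum(r[ages >= mm]), numeric(1))
    A <- F * adultFrac / denom
    list(adultFemales = stats::median(A), sd = stats::sd(A),
         range = range(A), realizations = A)
  })
}

#' Synthetic stable age distribution for a long-lived elasmobranch
#'
#' A labelled synthetic stand-in for an externally published stable age
#' distribution (which is not shipped here): proportions proportional to
#' cumulative survivorship under age-specific annual survival (lower in
#' the first two years, higher for older fish) up to a maximum age. It
#' reproduces the shape, not the values, of any particular published
#' vector.
#'
#' @param maxAge maximum age class.
#' @param survJuv annual survival for ages 0-1.
#' @param survAdult annual survival for ages 2+.
#' @return named numeric of proportions summing to 1 (names are ages).
#' @export
syntheticStableAge <- function(maxAge = 30L, survJuv = 0.55,
                               survAdult = 0.85) {
  surv <- c(rep(survJuv, 2), rep(survAdult, maxAge - 1L))
  lx <- cumprod(c(1, surv[seq_len(maxAge)]))
  stats::setNames(lx / sum(lx), 0:maxAge)
}
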