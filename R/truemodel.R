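#' Default ground-truth density model
#'
#' The data-generating model behind the synthetic surveys: a dome-shaped
#' thermal response peaking near 28 deg C, increasing affinity for
#' well-oxygenated water, a broad brackish salinity optimum, increasing
#' (saturating) affinity for concentrated mangrove habitat, a mild
#' log-linear interannual decline, a Gaussian bump of density a few
#' kilometres upriver, and a penalty for exclusively developed shorelines.
#' The intercept is calibrated so that, under the default scene, design and
#' environment, total juvenile catch over a 13-year survey is of the order
#' of a hundred fish across ~2500 sets — the sparse-catch regime this
#' pipeline is designed for.
#'
#' Any effect can be overridden, including with zero functions (useful for
#' uniform-density controls).
#'
#' @param intercept log-scale intercept (per yard-minute of effort).
#' @param fTemp,fDO,fSalin,fMNN,fYear,fDist smooth effect functions.
#' @param betaDeveloped additive developed-shoreline effect.
#' @param p Tweedie power in (1, 2).
#' @param phi Tweedie dispersion.
#' @return a [TrueModel-class].
#' @export
defaultTrueModel <- function(intercept = -11.4,
                             fTemp = function(x) -((x - 28) / 5.5)^2 + 0.4,
                             fDO = function(x) 0.35 * (x - 7),
                             fSalin = function(x) -0.6 * ((x - 16) / 14)^2,
                             fMNN = function(x) 0.0035 * pmin(x, 400) - 0.6,
                             fYear = function(y) -0.07 * (y - 2016),
                             fDist = function(d)
                               0.7 * exp(-((d - 1800) / 1200)^2),
                             betaDeveloped = -0.6,
                             p = 1.5, phi = 1.2) {
  new("TrueModel", intercept = intercept, fTemp = fTemp, fDO = fDO,
      fSalin = fSalin, fMNN = fMNN, fYear = fYear, fDist = fDist,
      betaDeveloped = betaDeveloped, p = p, phi = phi)
}

#' Evaluate the true linear predictor
#'
#' Computes `eta` for rows of a covariate table using a [TrueModel-class].
#' Expected catch for a set is then `effort * exp(eta)`.
#'
#' @param model a [TrueModel-class].
#' @param data data.frame with columns Avg_temp, Avg_DO, Avg_salin,
#'   Sum_MNN, Year, DistToRM, DevelopedSL.
#' @return numeric vector of linear-predictor values.
#' @export
trueLinearPredictor <- function(model, data) {
  eta <- model@intercept +
    model@fTemp(data$Avg_temp) + model@fDO(data$Avg_DO) +
    model@fSalin(data$Avg_salin) + model@fMNN(data$Sum_MNN) +
    model@fYear(data$Year) + model@fDist(data$DistToRM) +
    model@betaDeveloped * (as.numeric(as.character(data$DevelopedSL)) == 1)
  if (any(!is.finite(eta)))
    stop("true linear predictor is non-finite for some covariates")
  eta
}
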