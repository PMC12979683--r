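# shared fixtures, built once per test run and cached

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures))
    assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures)
}

# a compact estuary used by most unit tests
smallScene <- function() fixture("smallScene",
  generateScene(estuaryConfig(nx = 16L, ny = 16L), seed = 11))

smallEnv <- function() fixture("smallEnv",
  generateEnvironment(smallScene(),
                      seq(as.Date("2010-01-01"), as.Date("2013-12-31"),
                          by = "day"), seed = 12))

# four-year survey on the small scene under the default truth
smallSurvey <- function() fixture("smallSurvey",
  simulateSurvey(smallScene(), smallEnv(), defaultTrueModel(),
                 surveyDesign(years = 2010:2013), seed = 13))

# a truth model with every effect switched off (uniform density)
flatTrueModel <- function(intercept = -11.4, p = 1.5, phi = 1.2) {
  defaultTrueModel(intercept = intercept,
                   fTemp = function(x) 0 * x, fDO = function(x) 0 * x,
                   fSalin = function(x) 0 * x, fMNN = function(x) 0 * x,
                   fYear = function(y) 0 * y, fDist = function(d) 0 * d,
                   betaDeveloped = 0, p = p, phi = phi)
}

# moderately strong-signal fit on the small survey, shared across tests
smallFit <- function() fixture("smallFit",
  fitDensityModel(c("Avg_DO", "Avg_temp", "Sum_MNN"), smallSurvey()))

# a degenerate FitResult stub for selection-arithmetic tests
stubFit <- function(covs, aic) {
  new("FitResult", spec = modelSpec(covs), fit = NULL, aic = aic,
      devExpl = 0, power = 1.5, scale = 1, reml = 0, edf = numeric(0),
      n = 0L, converged = TRUE,
      aicDefinition = "conditional AIC of the penalized fit")
}
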