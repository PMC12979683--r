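#' @import methods
NULL

setClassUnion("listOrNULL", c("list", "NULL"))

#' EstuaryScene: a schematic synthetic estuary
#'
#' A gridded synthetic estuary: a rectangular harbor open to the sea on its
#' southern edge, fed by up to three linear rivers (labelled A, B, C, standing
#' in for the Myakka, Peace and Caloosahatchee) entering from the north. The
#' scene carries everything the survey and habitat modules need: per-cell
#' depth, the shoreline as a set of segments, a binary mangrove raster at
#' sub-cell resolution, river membership, and signed distance to the nearest
#' river mouth (negative seaward of the mouth).
#'
#' Cells are square "micro grids" (default 200 m). Coordinates are metres in
#' an arbitrary projected plane with origin at the south-west corner;
#' matrices are indexed `[ix, iy]` with `iy` increasing northward (upriver).
#'
#' @slot cellSize cell side length (m).
#' @slot nx,ny grid dimensions (cells).
#' @slot cellX,cellY cell-centre coordinates (m).
#' @slot water logical matrix; FALSE cells are land.
#' @slot depth numeric matrix, metres, >= 0 (0 on land).
#' @slot riverId character matrix in {"A","B","C"}: nearest river.
#' @slot distToRM numeric matrix, signed metres to nearest river mouth.
#' @slot developed logical matrix: cell shoreline exclusively developed.
#' @slot distShoreCell numeric matrix: cell centre to nearest shoreline (m).
#' @slot shoreline 4-column matrix of segments (x1, y1, x2, y2).
#' @slot riverMouths matrix of mouth coordinates, rownames "A","B","C".
#' @slot mangroveMask integer matrix at sub-cell resolution (0/1).
#' @slot distShorePix numeric matrix: mangrove-pixel centre to shoreline (m).
#' @slot pixelSize mangrove raster resolution (m).
#' @slot zonal data.frame of per-cell habitat covariates (Min_Depth,
#'   Sum_MNN, Min_MDTS, DistToRM, River, DevelopedSL).
#' @slot epoch first valid date of the scene.
#' @slot config the generating configuration list.
#' @slot seed generating seed.
#' @export
setClass("EstuaryScene",
  representation(cellSize = "numeric", nx = "integer", ny = "integer",
    cellX = "numeric", cellY = "numeric", water = "matrix",
    depth = "matrix", riverId = "matrix", distToRM = "matrix",
    developed = "matrix", distShoreCell = "matrix", shoreline = "matrix",
    riverMouths = "matrix", mangroveMask = "matrix",
    distShorePix = "matrix", pixelSize = "numeric", zonal = "data.frame",
    epoch = "Date", config = "list", seed = "integer"))

setValidity("EstuaryScene", function(object) {
  msg <- character()
  if (any(object@depth < 0, na.rm = TRUE)) msg <- c(msg, "depth must be >= 0")
  if (!all(dim(object@depth) == c(object@nx, object@ny)))
    msg <- c(msg, "depth dimensions disagree with nx, ny")
  if (!all(object@riverId %in% c("A", "B", "C")))
    msg <- c(msg, "riverId must be in {A, B, C}")
  mouthY <- object@config$mouthRow * object@cellSize
  cy <- matrix(object@cellY[col(object@distToRM)], object@nx, object@ny)
  if (!all((object@distToRM < 0) == (cy < mouthY)))
    msg <- c(msg, "distToRM must be negative exactly seaward of the mouth")
  if (length(msg)) msg else TRUE
})

#' TrueModel: known data-generating density model
#'
#' The ground-truth density surface used by the synthetic survey generator:
#' smooth effects for temperature, dissolved oxygen, salinity, mangrove
#' focal sum, year and distance to river mouth, a linear effect for the
#' developed-shoreline flag, an intercept, and Tweedie power/dispersion.
#' Expected catch for a set is `effort * exp(eta)` with `eta` the linear
#' predictor, and catches are exact Tweedie draws.
#'
#' @slot intercept intercept on the log scale (per yard-minute of effort).
#' @slot fTemp,fDO,fSalin,fMNN,fYear,fDist smooth effect functions.
#' @slot betaDeveloped additive effect when a set is in a developed cell.
#' @slot p Tweedie power, in (1, 2).
#' @slot phi Tweedie dispersion, > 0.
#' @export
setClass("TrueModel",
  representation(intercept = "numeric", fTemp = "function", fDO = "function",
    fSalin = "function", fMNN = "function", fYear = "function",
    fDist = "function", betaDeveloped = "numeric", p = "numeric",
    phi = "numeric"))

setValidity("TrueModel", function(object) {
  msg <- character()
  if (object@p <= 1 || object@p >= 2) msg <- c(msg, "p must be in (1, 2)")
  if (object@phi <= 0) msg <- c(msg, "phi must be > 0")
  if (length(msg)) msg else TRUE
})

#' SurveyDesign: random gillnet survey layout
#'
#' Stratified-random design mirroring a fishery-independent gillnet survey:
#' a fixed number of sets per month in each river region, on a small number
#' of trip dates per month, with nets of 30.5 or 61 m soaked for one hour.
#'
#' @slot setsPerMonth named numeric (per region A/B/C).
#' @slot tripsPerMonth trip dates per region per month.
#' @slot netLengthsM allowed net lengths (m).
#' @slot probShortNet probability the shorter net is used for a set.
#' @slot netHeightM net height (m); the field protocol records only length
#'   and mesh, so height is an explicit configurable, default 2.5 m.
#' @slot soakMinutes soak duration (min).
#' @slot years calendar years surveyed.
#' @export
setClass("SurveyDesign",
  representation(setsPerMonth = "numeric", tripsPerMonth = "integer",
    netLengthsM = "numeric", probShortNet = "numeric",
    netHeightM = "numeric", soakMinutes = "numeric", years = "integer"))

setValidity("SurveyDesign", function(object) {
  msg <- character()
  if (object@soakMinutes <= 0) msg <- c(msg, "soakMinutes must be > 0")
  if (any(object@netLengthsM <= 0)) msg <- c(msg, "net lengths must be > 0")
  if (object@netHeightM <= 0) msg <- c(msg, "netHeightM must be > 0")
  if (length(msg)) msg else TRUE
})

#' EnvFieldSeries: daily environmental fields over a scene
#'
#' Daily per-cell water temperature, dissolved oxygen, salinity and pH
#' surfaces with a sinusoidal seasonal component, an upriver salinity
#' gradient, and spatially smooth random variation. Fields are computed
#' deterministically on demand from (seed, date) by [envField()], so the
#' object stores only parameters, not the full space-time cube.
#'
#' @slot scene the parent [EstuaryScene-class].
#' @slot dates the covered date range (all days inclusive).
#' @slot seed generating seed.
#' @slot noiseAmp named amplitudes of the smooth random fields.
#' @slot envelopes named list of physical clipping ranges per variable.
#' @slot params list of deterministic mean-surface parameters.
#' @export
setClass("EnvFieldSeries",
  representation(scene = "EstuaryScene", dates = "Date", seed = "integer",
    noiseAmp = "numeric", envelopes = "list", params = "list"))

#' ClassSignature: per-class multiband signature
#'
#' Mean vector and band covariance of one land-cover class
#' (mangrove / other vegetation / non-vegetation), estimated from labelled
#' training pixels, as used by the maximum-likelihood classifier.
#'
#' @slot label class label.
#' @slot mean per-band mean vector.
#' @slot cov band covariance matrix (symmetric PSD; a small ridge is added
#'   when training pixels are degenerate).
#' @slot n number of training pixels.
#' @export
setClass("ClassSignature",
  representation(label = "character", mean = "numeric", cov = "matrix",
    n = "integer"))

setValidity("ClassSignature", function(object) {
  msg <- character()
  if (!isSymmetric(unname(object@cov), tol = 1e-8))
    msg <- c(msg, "covariance must be symmetric")
  ev <- eigen(object@cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) msg <- c(msg, "covariance must be PSD")
  if (object@n < length(object@mean) + 1L)
    msg <- c(msg, "need at least bands + 1 training pixels")
  if (length(msg)) msg else TRUE
})

#' ModelSpec: one candidate density-model specification
#'
#' A covariate subset for the Tweedie GAM, with each covariate's role:
#' continuous covariates enter as penalized smooths, Season / River /
#' DevelopedSL as parametric factors.
#'
#' @slot covariates included covariate names.
#' @slot smoothTerms subset fitted as smooths.
#' @slot parametricTerms subset fitted as parametric factors.
#' @export
setClass("ModelSpec",
  representation(covariates = "character", smoothTerms = "character",
    parametricTerms = "character"))

#' FitResult: one fitted Tweedie GAM density model
#'
#' Wraps the fitted \pkg{mgcv} model together with its specification and
#' the selection-relevant summaries. The reported AIC is the conditional
#' AIC of the penalized fit as returned by `AIC()` on the \pkg{mgcv} object
#' (effective-degrees-of-freedom corrected); this definition is recorded in
#' `aicDefinition`.
#'
#' @slot spec the [ModelSpec-class].
#' @slot fit the underlying mgcv fit.
#' @slot aic conditional AIC.
#' @slot devExpl percent deviance explained, `100 * (1 - D_model / D_null)`.
#' @slot power estimated Tweedie power.
#' @slot scale dispersion (scale) estimate.
#' @slot reml negative restricted (log-)likelihood criterion value.
#' @slot edf per-smooth effective degrees of freedom.
#' @slot n observations used (complete cases).
#' @slot converged logical; non-converged fits are excluded from selection.
#' @slot aicDefinition free-text definition of the AIC flavour reported.
#' @export
setClass("FitResult",
  representation(spec = "ModelSpec", fit = "ANY", aic = "numeric",
    devExpl = "numeric", power = "numeric", scale = "numeric",
    reml = "numeric", edf = "numeric", n = "integer", converged = "logical",
    aicDefinition = "character"))

setValidity("FitResult", function(object) {
  if (object@converged && !is.finite(object@aic)) "AIC must be finite" else TRUE
})

#' ValidationReport: internal and external validation summaries
#'
#' Produced by [crossValidate()] (per-fold RMSE and AUC with means and SDs)
#' and [externalValidate()] (per-sighting standardized scores, proportion
#' above zero, and a one-sample t-test of the mean score against zero).
#' Either part may be empty depending on which function built the report.
#'
#' @slot foldRMSE per-fold root mean squared error on counts.
#' @slot foldAUC per-fold area under the ROC curve.
#' @slot aucAtThreshold per-fold single-point AUC at the training-median
#'   prediction threshold, `(sensitivity + specificity) / 2`.
#' @slot external list with elements `scores`, `propAbove`, `t`, `df`, `p`,
#'   `mean`, `ci` (95%) when external validation was run.
#' @export
setClass("ValidationReport",
  representation(foldRMSE = "numeric", foldAUC = "numeric",
    aucAtThreshold = "numeric", external = "list"))

setValidity("ValidationReport", function(object) {
  msg <- character()
  if (length(object@foldAUC) &&
      any(object@foldAUC < 0 | object@foldAUC > 1, na.rm = TRUE))
    msg <- c(msg, "AUC must lie in [0, 1]")
  ext <- object@external
  if (length(ext)) {
    if (!is.null(ext$propAbove) && (ext$propAbove < 0 || ext$propAbove > 1))
      msg <- c(msg, "proportion above zero must lie in [0, 1]")
    if (!is.null(ext$df) && !is.null(ext$scores) &&
        ext$df != length(ext$scores) - 1L)
      msg <- c(msg, "external df must equal n_scores - 1")
  }
  if (length(msg)) msg else TRUE
})

#' PredictionGrid: nearshore extrapolation grid
#'
#' Micro-grid cells clipped to the nearshore sampling frame: within a
#' maximum distance of the shoreline (default 61 m) and at most a maximum
#' depth (default 3 m, the gillnet's limit; cells exactly at the boundary
#' are kept). Each cell carries its soak area (the clipped water area, in
#' square yards) and a flag for whether a survey set ever occurred in it.
#'
#' @slot cells data.frame with columns microgrid, ix, iy, x, y, areaFrac,
#'   soakAreaYd2, inUniverse and the static habitat covariates.
#' @slot maxShoreDistM,maxDepthM the clip rules used.
#' @export
setClass("PredictionGrid",
  representation(cells = "data.frame", maxShoreDistM = "numeric",
    maxDepthM = "numeric"))

setValidity("PredictionGrid", function(object) {
  if (nrow(object@cells) && any(object@cells$soakAreaYd2 <= 0))
    "all soak areas must be > 0" else TRUE
})

#' AbundanceDraws: posterior realizations of total abundance
#'
#' Total-abundance realizations indexed by posterior coefficient draw, year,
#' season and domain (`sampled` = cells where a survey set occurred;
#' `full` = the whole prediction grid). `retained` marks draws kept after
#' extreme-value trimming; seasonal and domain contrasts use the same draw
#' set, so they are paired at the draw level.
#'
#' @slot draws numeric array [draw, year, season, domain].
#' @slot retained logical array of the same shape (trimming mask).
#' @slot years,seasons,domains dimension labels.
#' @slot trimFactor draws above `trimFactor * median` were masked.
#' @slot meta list of provenance (sampler, n draws, reference soak minutes).
#' @export
setClass("AbundanceDraws",
  representation(draws = "array", retained = "array", years = "integer",
    seasons = "character", domains = "character", trimFactor = "numeric",
    meta = "list"))

setValidity("AbundanceDraws", function(object) {
  msg <- character()
  if (!identical(dim(object@draws), dim(object@retained)))
    msg <- c(msg, "draws and retained must have identical shape")
  kept <- object@draws[object@retained]
  if (length(kept) && (any(!is.finite(kept)) || any(kept <= 0)))
    msg <- c(msg, "retained draws must be positive and finite")
  if (length(msg)) msg else TRUE
})

#' DemographyConfig: back-calculation parameters
#'
#' Parameters of the two adult-female back-calculation approaches: the
#' brood-size range (7-14 pups per brood, one brood per female every
#' `reproCycleYears` years), the truncated-normal distribution of combined
#' age-0 + age-1 female abundance, the uniform integer maturity-age
#' distribution setting the lower bound of adulthood, and (for the
#' stable-age approach) a vector of stable-age proportions by age.
#'
#' @slot broodMin,broodMax pups per brood.
#' @slot reproCycleYears female reproductive cycle (years).
#' @slot femaleFraction fraction of juveniles that are female.
#' @slot tnMean,tnSD,tnA,tnB truncated-normal parameters for juvenile
#'   (age-0 + age-1) female abundance.
#' @slot maturityMin,maturityMax uniform integer bounds on age at maturity.
#' @slot stableAgeRatios named numeric of stable-age proportions (names are
#'   ages); may be empty for the brood-size approach.
#' @slot nRealizations Monte Carlo realizations.
#' @export
setClass("DemographyConfig",
  representation(broodMin = "numeric", broodMax = "numeric",
    reproCycleYears = "numeric", femaleFraction = "numeric",
    tnMean = "numeric", tnSD = "numeric", tnA = "numeric", tnB = "numeric",
    maturityMin = "integer", maturityMax = "integer",
    stableAgeRatios = "numeric", nRealizations = "integer"))

setValidity("DemographyConfig", function(object) {
  msg <- character()
  if (object@tnA >= object@tnB) msg <- c(msg, "tnA must be < tnB")
  if (object@broodMin > object@broodMax)
    msg <- c(msg, "broodMin must be <= broodMax")
  if (object@broodMin <= 0) msg <- c(msg, "brood sizes must be > 0")
  r <- object@stableAgeRatios
  if (length(r)) {
    if (any(r < 0)) msg <- c(msg, "stable-age ratios must be >= 0")
    if (abs(sum(r) - 1) > 1e-6) msg <- c(msg, "stable-age ratios must sum to 1")
    if (is.null(names(r))) msg <- c(msg, "stable-age ratios must be named by age")
  }
  if (length(msg)) msg else TRUE
})
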