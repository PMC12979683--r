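# Tweedie penalized-spline density model with log-effort offset,
# all-subsets enumeration and AIC selection.

CONTINUOUS_COVS <- c("Min_Depth", "Avg_DO", "Avg_temp", "Avg_salin",
                     "Avg_pH", "Min_MDTS", "Sum_MNN", "Year", "DistToRM")
FACTOR_COVS <- c("Season", "River", "DevelopedSL")

#' Build a model specification
#'
#' Splits a covariate subset into its roles: continuous covariates enter
#' the GAM as penalized smooths, Season/River/DevelopedSL as parametric
#' factors.
#'
#' @param covariates character vector of covariate names.
#' @return a [ModelSpec-class].
#' @export
modelSpec <- function(covariates) {
  covariates <- unique(covariates)
  unknown <- setdiff(covariates, c(CONTINUOUS_COVS, FACTOR_COVS))
  if (length(unknown))
    stop("unknown covariates: ", paste(unknown, collapse = ", "))
  new("ModelSpec", covariates = covariates,
      smoothTerms = intersect(covariates, CONTINUOUS_COVS),
      parametricTerms = intersect(covariates, FACTOR_COVS))
}

# pairwise Pearson correlation on numeric-coerced covariates, complete cases
covariateCorrelation <- function(data, covariates) {
  num <- sapply(data[covariates], function(v)
    if (is.numeric(v)) v else as.numeric(as.factor(v)))
  stats::cor(num, use = "pairwise.complete.obs")
}

#' Enumerate candidate model specifications
#'
#' Generates all subsets of the toggleable candidate covariates (2^k specs
#' with `alwaysInclude` terms present in every one), then removes any spec
#' containing a covariate pair whose Pearson correlation exceeds the
#' collinearity threshold on the fitting data (complete cases). Constant
#' covariates are dropped from the candidate list with a warning. With 10
#' toggleable candidates the enumeration has 1024 subsets before the
#' collinearity filter; the pre-filter count is kept in attribute
#' `nBeforeFilter` and the offending pairs in `droppedPairs`.
#'
#' @param candidates candidate covariate names (nonempty).
#' @param data the fitting table.
#' @param alwaysInclude covariates forced into every spec.
#' @param corThreshold collinearity cutoff on `|rho|` (default 0.7).
#' @return list of [ModelSpec-class] with attributes `nBeforeFilter`,
#'   `droppedPairs`.
#' @export
enumerateSpecs <- function(candidates, data, alwaysInclude = character(),
                           corThreshold = 0.7) {
  if (!length(candidates)) stop("candidate list must be nonempty")
  keep <- vapply(candidates, function(v) {
    ok <- length(unique(stats::na.omit(data[[v]]))) > 1L
    if (!ok) warning("constant covariate '", v, "' dropped from candidates")
    ok
  }, logical(1))
  candidates <- candidates[keep]
  toggle <- setdiff(candidates, alwaysInclude)
  k <- length(toggle)
  if (k > 16L) stop("more than 16 toggleable candidates")
  all <- union(alwaysInclude, toggle)
  rho <- covariateCorrelation(data, all)
  badPairs <- which(abs(rho) > corThreshold & upper.tri(rho), arr.ind = TRUE)
  bad <- lapply(seq_len(nrow(badPairs)), function(i)
    c(rownames(rho)[badPairs[i, 1]], colnames(rho)[badPairs[i, 2]]))
  specs <- list()
  nTotal <- 2^k
  for (m in seq_len(nTotal) - 1L) {
    covs <- union(alwaysInclude, toggle[bitwAnd(m, 2^(seq_len(k) - 1L)) > 0])
    ok <- !any(vapply(bad, function(pr) all(pr %in% covs), logical(1)))
    if (ok) specs[[length(specs) + 1L]] <- modelSpec(covs)
  }
  attr(specs, "nBeforeFilter") <- nTotal
  attr(specs, "droppedPairs") <- bad
  specs
}

# per-term basis dimension, capped below the number of unique values
smoothK <- function(data, term, k) {
  max(3L, min(k, length(unique(stats::na.omit(data[[term]]))) - 1L))
}

specFormula <- function(spec, data, k) {
  terms <- c(
    vapply(spec@smoothTerms, function(tm)
      sprintf("s(%s, k = %d)", tm, smoothK(data, tm, k)), character(1)),
    spec@parametricTerms)
  # the Tweedie family resolves internal mgcv helpers through the formula
  # environment, so parent it on the mgcv namespace
  stats::as.formula(paste("nCaught ~",
                          paste(c("1", terms), collapse = " + "),
                          "+ offset(log(effort))"),
                    env = new.env(parent = asNamespace("mgcv")))
}

#' Fit one Tweedie GAM density model
#'
#' Fits `log mu_i = log(effort_i) + beta0 + sum_j f_j(x_ij) + parametric
#' terms` by penalized thin-plate regression splines, with the Tweedie
#' power and all smoothing parameters chosen by REML (\pkg{mgcv}'s `tw()`
#' family). Complete-case analysis: rows missing any used covariate are
#' excluded. Non-convergence yields a flagged [FitResult-class] that
#' [selectBest()] excludes.
#'
#' @param spec a [ModelSpec-class] (or character vector of covariates).
#' @param data survey table with `nCaught` and `effort` columns.
#' @param k basis dimension per smooth (default 10, reduced automatically
#'   when a covariate has few distinct values).
#' @return a [FitResult-class].
#' @export
fitDensityModel <- function(spec, data, k = 10) {
  if (is.character(spec)) spec <- modelSpec(spec)
  data <- canonicalFactors(data)
  used <- c("nCaught", "effort", spec@covariates)
  data <- data[stats::complete.cases(data[used]), , drop = FALSE]
  nSm <- length(spec@smoothTerms)
  if (nSm > 0 && nrow(data) < 10 * nSm)
    stop("need at least 10 observations per estimated smooth")
  fml <- specFormula(spec, data, k)
  fit <- tryCatch(
    mgcv::gam(fml, family = mgcv::tw(), method = "REML", data = data),
    error = function(e) e)
  if (inherits(fit, "error") || !fit$converged) {
    return(new("FitResult", spec = spec, fit = NULL, aic = NA_real_,
               devExpl = NA_real_, power = NA_real_, scale = NA_real_,
               reml = NA_real_, edf = numeric(0), n = nrow(data),
               converged = FALSE,
               aicDefinition = "conditional AIC of the penalized fit"))
  }
  sm <- summary(fit)
  pw <- as.numeric(sub(".*p=([0-9.]+).*", "\\1", fit$family$family))
  new("FitResult", spec = spec, fit = fit, aic = stats::AIC(fit),
      devExpl = 100 * sm$dev.expl, power = pw, scale = sm$scale,
      reml = as.numeric(fit$gcv.ubre), edf = as.numeric(sm$edf),
      n = nrow(data), converged = TRUE,
      aicDefinition = "conditional AIC of the penalized fit")
}

#' Predict expected counts on new data
#'
#' Returns `mu = soakArea * exp(eta)` with delta-method standard errors
#' `se(mu) = mu * se(eta)` from the coefficient covariance. Rows whose
#' smooth covariates fall beyond the fitted range by more than
#' `extrapolationGuard` times the range are flagged, not refused.
#'
#' @param fitres a converged [FitResult-class].
#' @param newdata covariate table (no effort column needed).
#' @param soakArea per-row soak area playing the role of effort (yd^2-min
#'   for survey sets; polygon soak area for prediction cells). A zero soak
#'   area gives a zero prediction.
#' @param extrapolationGuard allowed relative excursion beyond the fitted
#'   covariate range before flagging.
#' @return data.frame with columns mu, se, extrapolated.
#' @export
predictDensity <- function(fitres, newdata, soakArea,
                           extrapolationGuard = 0.1) {
  stopifnot(is(fitres, "FitResult"), fitres@converged)
  newdata <- canonicalFactors(newdata)
  newdata$effort <- rep_len(pmax(soakArea, 1e-300), nrow(newdata))
  pr <- mgcv::predict.gam(fitres@fit, newdata = newdata, type = "link",
                          se.fit = TRUE)
  mu <- as.numeric(exp(pr$fit)) * (rep_len(soakArea, nrow(newdata)) > 0)
  se <- mu * as.numeric(pr$se.fit)
  extra <- rep(FALSE, nrow(newdata))
  for (tm in fitres@spec@smoothTerms) {
    r <- range(fitres@fit$model[[tm]])
    slack <- extrapolationGuard * diff(r)
    extra <- extra | newdata[[tm]] < r[1] - slack |
      newdata[[tm]] > r[2] + slack
  }
  data.frame(mu = mu, se = se, extrapolated = extra)
}

#' Select the best-performing model
#'
#' Among converged fits, takes the near-best set (AIC within 2 points of
#' the minimum) and picks the member with the highest cross-validated AUC;
#' ties (within 1e-8) break to fewer covariates, then lower AIC. With a
#' single near-best fit, or `cv = FALSE`, the minimum-AIC fit wins
#' directly.
#'
#' @param fits list of [FitResult-class].
#' @param data the fitting table (needed for cross-validation).
#' @param cv cross-validate the near-best set?
#' @param nFolds folds for [crossValidate()].
#' @param seed fold-assignment seed.
#' @param k basis dimension passed through to refits.
#' @return list with elements `best` (a [FitResult-class]), `nearBest`
#'   (list), and `table` (AIC/AUC summary data.frame).
#' @export
selectBest <- function(fits, data = NULL, cv = TRUE, nFolds = 10, seed = 1L,
                       k = 10) {
  fits <- Filter(function(f) f@converged, fits)
  if (!length(fits)) stop("no converged fits to select from")
  aic <- vapply(fits, function(f) f@aic, numeric(1))
  near <- fits[aic <= min(aic) + 2]
  nearAic <- aic[aic <= min(aic) + 2]
  aucs <- rep(NA_real_, length(near))
  if (cv && length(near) > 1L) {
    if (is.null(data)) stop("'data' is required for cross-validated selection")
    aucs <- vapply(seq_along(near), function(i) {
      vr <- crossValidate(near[[i]]@spec, data, nFolds = nFolds,
                          seed = seed, k = k)
      mean(vr@foldAUC, na.rm = TRUE)
    }, numeric(1))
    ord <- order(-round(aucs / 1e-8),
                 vapply(near, function(f) length(f@spec@covariates),
                        numeric(1)),
                 nearAic)
  } else {
    ord <- order(nearAic,
                 vapply(near, function(f) length(f@spec@covariates),
                        numeric(1)))
  }
  tab <- data.frame(
    covariates = vapply(near, function(f)
      paste(f@spec@covariates, collapse = "+"), character(1)),
    aic = nearAic, cvAUC = aucs)
  list(best = near[[ord[1]]], nearBest = near, table = tab[ord, ])
}
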