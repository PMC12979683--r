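# Internal cross-validation and sighting-based external validation.

# full-ROC AUC of predictions against a binary outcome; equals the
# Mann-Whitney statistic P(pred_pos > pred_neg) + 0.5 P(tie)
rocAUC <- function(positive, pred) {
  roc <- pROC::roc(response = positive, predictor = pred, quiet = TRUE,
                   direction = "<", levels = c(FALSE, TRUE))
  as.numeric(pROC::auc(roc))
}

#' Ten-fold cross-validation of a model specification
#'
#' Random k-fold partition, stratified on presence/absence so every fold
#' contains positive sets whenever possible. Per fold the model is refit on
#' the training portion and held-out expected counts are predicted with the
#' sets' own effort; reported are the RMSE on counts, the full-ROC AUC of
#' predictions against the binary outcome (catch > 0), and the single-point
#' AUC at the operating threshold defined by the median training-set
#' prediction (the pseudo-binary classification threshold). Folds whose
#' held-out portion has no positives (or no negatives) have undefined AUC
#' and are excluded with a warning. Deterministic given (data, seed).
#'
#' @param spec a [ModelSpec-class] or character vector of covariates.
#' @param data survey table.
#' @param nFolds number of folds (default 10).
#' @param seed fold-assignment seed.
#' @param k basis dimension per smooth.
#' @return a [ValidationReport-class] with the internal slots filled.
#' @export
crossValidate <- function(spec, data, nFolds = 10, seed = 1L, k = 10) {
  if (is.character(spec)) spec <- modelSpec(spec)
  data <- canonicalFactors(data)
  used <- c("nCaught", "effort", spec@covariates)
  data <- data[stats::complete.cases(data[used]), , drop = FALSE]
  n <- nrow(data)
  fold <- integer(n)
  pos <- which(data$nCaught > 0)
  neg <- which(data$nCaught == 0)
  withSeed(childSeed(seed, 5L), {
    fold[pos] <- 1L + (sample(seq_along(pos)) - 1L) %% nFolds
    fold[neg] <- 1L + (sample(seq_along(neg)) - 1L) %% nFolds
  })
  rmse <- auc <- aucThr <- rep(NA_real_, nFolds)
  for (f in seq_len(nFolds)) {
    tr <- data[fold != f, , drop = FALSE]
    te <- data[fold == f, , drop = FALSE]
    fitres <- fitDensityModel(spec, tr, k = k)
    if (!fitres@converged) next
    pred <- predictDensity(fitres, te, soakArea = te$effort)$mu
    rmse[f] <- sqrt(mean((pred - te$nCaught)^2))
    obsPos <- te$nCaught > 0
    if (length(unique(obsPos)) < 2L) {
      warning("fold ", f, " lacks both outcome classes; AUC undefined")
      next
    }
    auc[f] <- rocAUC(obsPos, pred)
    thr <- stats::median(predictDensity(fitres, tr,
                                        soakArea = tr$effort)$mu)
    sens <- mean(pred[obsPos] > thr)
    spcf <- mean(pred[!obsPos] <= thr)
    aucThr[f] <- (sens + spcf) / 2
  }
  new("ValidationReport", foldRMSE = rmse, foldAUC = auc,
      aucAtThreshold = aucThr, external = list())
}

#' External validation against independent sightings
#'
#' Scores each independent sighting by comparing the model prediction at
#' its location and date against the domain-wide daily prediction
#' distribution over valid water depths (0-3 m by default). In the default
#' `ratio` mode the score is `pred(sighting) / median(domain preds) - 1`,
#' so scores are centred at zero by construction and invariant to scaling
#' all predictions by a positive constant; in `zscore` mode the prediction
#' is standardized by the daily domain mean and SD instead. Reported are
#' the proportion of scores above zero (the consistency measure: uniform
#' random locations give about one half) and a one-sample t-test of the
#' mean score against zero with a 95% CI. Days whose domain median is zero
#' are skipped with a warning.
#'
#' @param fitres a converged [FitResult-class].
#' @param sightings data.frame from [simulateSightings()] (needs columns
#'   date and microgrid).
#' @param env the [EnvFieldSeries-class] supplying daily fields.
#' @param depthRange valid water depths (m) defining the domain cells.
#' @param zscoreMode "ratio" (default) or "zscore".
#' @return a [ValidationReport-class] with the `external` slot filled.
#' @export
externalValidate <- function(fitres, sightings, env,
                             depthRange = c(0, 3),
                             zscoreMode = c("ratio", "zscore")) {
  zscoreMode <- match.arg(zscoreMode)
  sc <- env@scene
  cells <- sc@zonal
  valid <- which(cells$water & cells$Min_Depth > depthRange[1] &
                   cells$Min_Depth <= depthRange[2])
  idxMat <- cbind(cells$ix[valid], cells$iy[valid])
  scores <- numeric(0)
  for (d in split(seq_len(nrow(sightings)), as.character(sightings$date))) {
    date <- sightings$date[d[1]]
    f <- envField(env, date)
    nd <- data.frame(Avg_temp = f$temp[idxMat], Avg_DO = f$do[idxMat],
                     Avg_salin = f$salin[idxMat], Avg_pH = f$ph[idxMat],
                     Min_Depth = cells$Min_Depth[valid],
                     Sum_MNN = cells$Sum_MNN[valid],
                     Min_MDTS = cells$Min_MDTS[valid],
                     Year = as.integer(strftime(date, "%Y")),
                     Season = as.character(assignSeason(date)),
                     River = cells$River[valid],
                     DistToRM = cells$DistToRM[valid],
                     DevelopedSL = cells$DevelopedSL[valid])
    pred <- predictDensity(fitres, nd, soakArea = 1)$mu
    pos <- match(sightings$microgrid[d], cells$microgrid[valid])
    if (anyNA(pos)) stop("sighting outside the valid-depth domain")
    if (zscoreMode == "ratio") {
      med <- stats::median(pred)
      if (!is.finite(med) || med <= 0) {
        warning("daily median prediction is zero on ", date,
                "; sightings skipped")
        next
      }
      scores <- c(scores, pred[pos] / med - 1)
    } else {
      mu <- mean(pred); sd <- stats::sd(pred)
      if (!is.finite(sd) || sd == 0) {
        warning("degenerate daily prediction field on ", date,
                "; sightings skipped")
        next
      }
      scores <- c(scores, (pred[pos] - mu) / sd)
    }
  }
  tt <- tryCatch(stats::t.test(scores, mu = 0), error = function(e) NULL)
  new("ValidationReport", foldRMSE = numeric(0), foldAUC = numeric(0),
      aucAtThreshold = numeric(0),
      external = list(scores = scores, propAbove = mean(scores > 0),
                      t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
                      df = length(scores) - 1L,
                      p = if (is.null(tt)) NA_real_ else tt$p.value,
                      mean = mean(scores),
                      ci = if (is.null(tt)) c(NA_real_, NA_real_) else
                        as.numeric(tt$conf.int),
                      mode = zscoreMode))
}
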