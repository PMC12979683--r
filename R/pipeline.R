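# End-to-end orchestration: configuration, staged runner, logging.

#' Assemble a run configuration
#'
#' A fully serializable description of an end-to-end run: scene geometry,
#' survey design, ground-truth model parameters (applied to
#' [defaultTrueModel()]), model-selection options, validation and
#' abundance options, demography parameters and the master seed. The
#' configuration round-trips losslessly through YAML
#' ([writeRunConfigYAML()] / [readRunConfigYAML()]), and every output file
#' of [runPipeline()] carries its hash.
#'
#' @param scene from [estuaryConfig()].
#' @param design a [SurveyDesign-class].
#' @param trueModelParams list overriding scalar arguments of
#'   [defaultTrueModel()] (`intercept`, `p`, `phi`, `betaDeveloped`).
#' @param candidates candidate covariates toggled in enumeration.
#' @param alwaysInclude covariates present in every candidate model; the
#'   default keeps DevelopedSL and Year in all specs (the shoreline state
#'   and the interannual trend carrier).
#' @param corThreshold collinearity cutoff.
#' @param k basis dimension per smooth.
#' @param cv cross-validate the near-best AIC set during selection?
#' @param nFolds cross-validation folds.
#' @param nSightings independent sightings simulated for external
#'   validation.
#' @param nDraws posterior draws.
#' @param sampler posterior sampler ("mh" or "gaussian").
#' @param trimFactor extreme-value trimming factor.
#' @param envStride day step for season-mean environmental fields.
#' @param demography a [DemographyConfig-class].
#' @param seed master seed.
#' @return a list of class `sawfishRunConfig`.
#' @export
runConfig <- function(scene = estuaryConfig(), design = surveyDesign(),
                      trueModelParams = list(),
                      candidates = c("Avg_DO", "Avg_temp", "Avg_salin",
                                     "Sum_MNN", "DistToRM"),
                      alwaysInclude = c("DevelopedSL", "Year"),
                      corThreshold = 0.7, k = 10, cv = TRUE, nFolds = 10,
                      nSightings = 200L, nDraws = 1000L, sampler = "mh",
                      trimFactor = 100, envStride = 15,
                      demography = demographyConfig(), seed = 1L) {
  structure(list(scene = scene,
                 design = list(setsPerMonth = design@setsPerMonth,
                               tripsPerMonth = design@tripsPerMonth,
                               netLengthsM = design@netLengthsM,
                               probShortNet = design@probShortNet,
                               netHeightM = design@netHeightM,
                               soakMinutes = design@soakMinutes,
                               years = design@years),
                 trueModelParams = trueModelParams,
                 candidates = candidates, alwaysInclude = alwaysInclude,
                 corThreshold = corThreshold, k = k, cv = cv,
                 nFolds = nFolds, nSightings = as.integer(nSightings),
                 nDraws = as.integer(nDraws), sampler = sampler,
                 trimFactor = trimFactor, envStride = envStride,
                 demography = list(broodMin = demography@broodMin,
                                   broodMax = demography@broodMax,
                                   tnMean = demography@tnMean,
                                   tnSD = demography@tnSD,
                                   tnA = demography@tnA,
                                   tnB = demography@tnB,
                                   nRealizations =
                                     demography@nRealizations),
                 seed = as.integer(seed)),
            class = "sawfishRunConfig")
}

#' Hash of a run configuration
#'
#' Stable content hash stamped into every pipeline output file.
#'
#' @param config a `sawfishRunConfig`.
#' @return hash string.
#' @export
configHash <- function(config) {
  cfg <- unclass(config)
  cfg$scene$epoch <- as.character(cfg$scene$epoch)
  # integer/double storage is not meaningful configuration content (and
  # differs after a YAML round trip), so hash everything as double
  cfg <- rapply(cfg, function(x)
    if (is.numeric(x)) as.numeric(x + 0) else x, how = "replace")
  rlang::hash(cfg)
}

configSerializable <- function(config) {
  cfg <- unclass(config)
  cfg$scene$epoch <- as.character(cfg$scene$epoch)
  cfg
}

#' Write / read a run configuration as YAML
#'
#' @param config a `sawfishRunConfig`.
#' @param path YAML file path.
#' @return `readRunConfigYAML` returns the reconstructed
#'   `sawfishRunConfig`.
#' @export
writeRunConfigYAML <- function(config, path) {
  out <- configSerializable(config)
  out$config_hash <- configHash(config)
  yaml::write_yaml(out, path)
}

#' @rdname writeRunConfigYAML
#' @export
readRunConfigYAML <- function(path) {
  y <- yaml::read_yaml(path)
  y$config_hash <- NULL
  sc <- y$scene
  sc$epoch <- as.Date(sc$epoch)
  sc$riverFrac <- unlist(sc$riverFrac)
  runConfig(scene = do.call(estuaryConfig, sc),
            design = surveyDesign(
              setsPerMonth = unlist(y$design$setsPerMonth),
              tripsPerMonth = y$design$tripsPerMonth,
              netLengthsM = unlist(y$design$netLengthsM),
              probShortNet = y$design$probShortNet,
              netHeightM = y$design$netHeightM,
              soakMinutes = y$design$soakMinutes,
              years = unlist(y$design$years)),
            trueModelParams = y$trueModelParams %||% list(),
            candidates = as.character(unlist(y$candidates)),
            alwaysInclude = as.character(unlist(y$alwaysInclude)),
            corThreshold = y$corThreshold, k = y$k, cv = y$cv,
            nFolds = y$nFolds, nSightings = y$nSightings,
            nDraws = y$nDraws, sampler = y$sampler,
            trimFactor = y$trimFactor, envStride = y$envStride,
            demography = do.call(demographyConfig, y$demography),
            seed = y$seed)
}

configTrueModel <- function(config) {
  do.call(defaultTrueModel, config$trueModelParams)
}

configDesign <- function(config) {
  do.call(surveyDesign, config$design)
}

configDemography <- function(config) {
  do.call(demographyConfig, config$demography)
}

#' Run the full analysis pipeline
#'
#' Executes the workflow end to end — scene and environment generation,
#' survey simulation, model enumeration/fitting/selection, internal and
#' external validation, posterior-simulation abundance with trend tests,
#' and demographic back-calculation — writing each stage's outputs as
#' plain open formats (CSV / GeoJSON / JSON / YAML) into `outDir`, plus a
#' log of versions, seeds and decisions. Any stage failure aborts with a
#' stage-tagged error. Runs are deterministic given the configuration.
#'
#' `fromStage` restarts at a later stage, reloading the survey table from
#' the output directory; upstream deterministic objects (scene,
#' environment) are regenerated from the configuration.
#'
#' @param config from [runConfig()].
#' @param outDir output directory (created if needed).
#' @param fromStage first stage to execute (1 scene, 2 survey, 3 fit,
#'   4 validate, 5 abundance, 6 demography).
#' @return invisibly, a list with the principal objects of every stage.
#' @export
runPipeline <- function(config, outDir, fromStage = 1L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  hash <- configHash(config)
  logPath <- file.path(outDir, "run.log")
  logf <- function(...) cat(..., "\n", sep = "", file = logPath,
                            append = TRUE)
  if (fromStage <= 1L) cat("", file = logPath)
  logf("run started: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  logf("package version: ",
       as.character(utils::packageVersion("sawfishDSM")))
  logf("config hash: ", hash, "; master seed: ", config$seed)
  stage <- function(name, expr) {
    logf("stage ", name, " started")
    tryCatch(expr, error = function(e)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
  }
  res <- list(hash = hash)

  # stage 1: scene + environment (deterministic; always regenerated)
  res$scene <- stage("scene", generateScene(config$scene, seed = config$seed))
  design <- configDesign(config)
  dates <- seq(as.Date(sprintf("%d-01-01", min(design@years))),
               as.Date(sprintf("%d-12-31", max(design@years))), by = "day")
  res$env <- stage("scene",
                   generateEnvironment(res$scene, dates,
                                       seed = childSeed(config$seed, 11L)))
  trueModel <- configTrueModel(config)
  if (fromStage <= 1L) {
    stage("scene", {
      writeRunConfigYAML(config, file.path(outDir, "config.yaml"))
      writeSceneGeoJSON(res$scene, file.path(outDir, "scene.geojson"), hash)
      writeRasterCSV(res$scene@depth, file.path(outDir, "depth.csv"), hash)
      writeRasterCSV(res$scene@mangroveMask,
                     file.path(outDir, "mangrove.csv"), hash)
    })
  }

  # stage 2: survey simulation
  surveyPath <- file.path(outDir, "survey.csv")
  if (fromStage <= 2L) {
    res$survey <- stage("survey", {
      s <- simulateSurvey(res$scene, res$env, trueModel, design,
                          seed = childSeed(config$seed, 12L))
      writeSurveyCSV(s, surveyPath, hash)
      s
    })
    logf("stage survey: ", nrow(res$survey), " sets, ",
         sum(res$survey$nCaught), " juveniles caught")
  } else {
    res$survey <- stage("survey", readSurveyCSV(surveyPath))
  }

  # stage 3: enumeration, fitting, selection
  res$selection <- stage("fit", {
    specs <- enumerateSpecs(config$candidates, res$survey,
                            alwaysInclude = config$alwaysInclude,
                            corThreshold = config$corThreshold)
    fits <- lapply(specs, fitDensityModel, data = res$survey, k = config$k)
    sel <- selectBest(fits, res$survey, cv = config$cv,
                      nFolds = config$nFolds,
                      seed = childSeed(config$seed, 13L), k = config$k)
    writeFitJSON(sel$best, file.path(outDir, "fit_best.json"), hash)
    logf("stage fit: ", length(specs), " specs (",
         attr(specs, "nBeforeFilter"), " before collinearity filter); ",
         "best AIC ", sprintf("%.2f", sel$best@aic))
    sel
  })

  # stage 4: validation
  res$validation <- stage("validate", {
    cvRep <- crossValidate(res$selection$best@spec, res$survey,
                           nFolds = config$nFolds,
                           seed = childSeed(config$seed, 14L), k = config$k)
    sightings <- simulateSightings(res$scene, res$env, trueModel,
                                   n = config$nSightings,
                                   seed = childSeed(config$seed, 15L))
    extRep <- externalValidate(res$selection$best, sightings, res$env)
    rep <- list(
      rmse_mean = mean(cvRep@foldRMSE, na.rm = TRUE),
      rmse_sd = stats::sd(cvRep@foldRMSE, na.rm = TRUE),
      auc_mean = mean(cvRep@foldAUC, na.rm = TRUE),
      auc_sd = stats::sd(cvRep@foldAUC, na.rm = TRUE),
      external_prop_above = extRep@external$propAbove,
      external_t = extRep@external$t, external_df = extRep@external$df,
      external_p = extRep@external$p, config_hash = hash)
    jsonlite::write_json(rep, file.path(outDir, "validation.json"),
                         auto_unbox = TRUE, digits = NA)
    list(internal = cvRep, external = extRep)
  })

  # stage 5: abundance
  res$abundance <- stage("abundance", {
    grid <- buildPredictionGrid(res$scene, res$survey)
    draws <- samplePosterior(res$selection$best, n = config$nDraws,
                             seed = childSeed(config$seed, 16L),
                             sampler = config$sampler)
    ad <- estimateAbundance(draws, res$selection$best, grid, res$env,
                            years = design@years,
                            trimFactor = config$trimFactor,
                            envStride = config$envStride)
    summ <- summarizeAbundance(ad)
    draws_df <- do.call(rbind, lapply(seq_along(ad@years), function(yi)
      do.call(rbind, lapply(seq_along(ad@seasons), function(si)
        do.call(rbind, lapply(seq_along(ad@domains), function(di)
          data.frame(draw = seq_len(dim(ad@draws)[1]),
                     year = ad@years[yi], season = ad@seasons[si],
                     domain = ad@domains[di],
                     total = ad@draws[, yi, si, di],
                     retained = ad@retained[, yi, si, di])))))))
    con <- file(file.path(outDir, "abundance_draws.csv"), "w")
    writeLines(paste0("# config_hash: ", hash), con)
    utils::write.csv(draws_df, con, row.names = FALSE)
    close(con)
    cmp <- compareYears(ad)
    chg <- interannualChange(ad)
    jsonlite::write_json(list(summary = summ, letters = cmp$letters,
                              change_mean = chg$mean, change_sd = chg$sd,
                              change_range = chg$range,
                              config_hash = hash),
                         file.path(outDir, "abundance_summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    list(grid = grid, draws = ad, summary = summ, letters = cmp$letters,
         change = chg)
  })

  # stage 6: demography
  res$demography <- stage("demography", {
    dcfg <- configDemography(config)
    dcfg@stableAgeRatios <- syntheticStableAge()
    bs <- broodsizeBackcalc(config = dcfg, mode = "summary")
    bmc <- broodsizeBackcalc(config = dcfg, mode = "mc",
                             seed = childSeed(config$seed, 17L))
    sa <- stableAgeBackcalc(dcfg, seed = childSeed(config$seed, 18L))
    out <- list(broodsize_summary = bs[c("adultFemales", "range")],
                broodsize_mc = list(median = bmc$adultFemales, sd = bmc$sd,
                                    range = bmc$range),
                stable_age = list(median = sa$adultFemales, sd = sa$sd,
                                  range = sa$range,
                                  ratios = "synthetic stand-in"),
                config_hash = hash)
    jsonlite::write_json(out, file.path(outDir, "demography.json"),
                         auto_unbox = TRUE, digits = NA)
    out
  })
  logf("run finished: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  invisible(res)
}
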