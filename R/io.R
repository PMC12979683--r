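# Plain-text serialization: survey tables and zonal tables as CSV, grids
# and shorelines as GeoJSON, fits and reports as JSON, configs as YAML.
# Every file carries the run configuration hash.

fmtNum <- function(x) {
  ifelse(is.na(x), "", sprintf("%.17g", x))
}

# survey-table column dictionary: canonical name -> file column
SURVEY_COLS <- c(setId = "set_id", date = "date", x = "x", y = "y",
  microgrid = "microgrid_id", effort = "effort_yard_min",
  Min_Depth = "depth_min_m", Avg_temp = "avg_temp", Avg_DO = "avg_do",
  Avg_salin = "avg_salin", Avg_pH = "avg_ph", Sum_MNN = "sum_mnn",
  Min_MDTS = "min_mdts", River = "river", DistToRM = "dist_to_rm_m",
  DevelopedSL = "developed_sl", nCaught = "n_caught",
  lengthsSTL = "lengths_stl_m", sexes = "sexes")

#' Write a survey table to CSV
#'
#' Writes the documented column dictionary (ISO-8601 dates, yard-minute
#' effort, semicolon-joined per-fish lengths and sexes) at full numeric
#' precision so that a read-back reproduces downstream results exactly.
#' The first line is a `# config_hash:` comment.
#'
#' @param survey table from [simulateSurvey()].
#' @param path output file.
#' @param hash configuration hash string recorded in the header comment.
#' @export
writeSurveyCSV <- function(survey, path, hash = "") {
  out <- survey[intersect(names(SURVEY_COLS), names(survey))]
  names(out) <- SURVEY_COLS[names(out)]
  for (nm in names(out)) {
    if (is.numeric(out[[nm]]) && nm != "n_caught" && nm != "microgrid_id")
      out[[nm]] <- fmtNum(out[[nm]])
  }
  out$date <- as.character(out$date)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  utils::write.csv(out, con, row.names = FALSE, quote = TRUE)
}

#' Read a survey table written by [writeSurveyCSV()]
#'
#' @param path the CSV file.
#' @return the survey table with canonical column names and types.
#' @export
readSurveyCSV <- function(path) {
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                       colClasses = c(lengths_stl_m = "character",
                                      sexes = "character"))
  inv <- stats::setNames(names(SURVEY_COLS), SURVEY_COLS)
  names(d) <- inv[names(d)]
  d$date <- as.Date(d$date)
  d$Season <- as.character(assignSeason(d$date))
  d$Year <- as.integer(strftime(d$date, "%Y"))
  d$lengthsSTL[is.na(d$lengthsSTL)] <- ""
  d$sexes[is.na(d$sexes)] <- ""
  d
}

#' Write scene grid polygons as GeoJSON
#'
#' Emits one square Polygon feature per water cell with its habitat
#' properties, plus the shoreline as a MultiLineString feature.
#'
#' @param scene an [EstuaryScene-class].
#' @param path output file.
#' @param hash configuration hash recorded as a foreign member.
#' @export
writeSceneGeoJSON <- function(scene, path, hash = "") {
  cs <- scene@cellSize
  cells <- scene@zonal[scene@zonal$water, ]
  feats <- lapply(seq_len(nrow(cells)), function(i) {
    x0 <- cells$x[i] - cs / 2; y0 <- cells$y[i] - cs / 2
    ring <- list(c(x0, y0), c(x0 + cs, y0), c(x0 + cs, y0 + cs),
                 c(x0, y0 + cs), c(x0, y0))
    list(type = "Feature",
         properties = list(microgrid = cells$microgrid[i],
                           min_depth_m = cells$Min_Depth[i],
                           river = cells$River[i],
                           dist_to_rm_m = cells$DistToRM[i],
                           developed_sl = cells$DevelopedSL[i],
                           sum_mnn = cells$Sum_MNN[i],
                           min_mdts = cells$Min_MDTS[i]),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  shore <- lapply(seq_len(nrow(scene@shoreline)), function(i)
    list(as.numeric(scene@shoreline[i, 1:2]),
         as.numeric(scene@shoreline[i, 3:4])))
  feats[[length(feats) + 1L]] <- list(
    type = "Feature", properties = list(layer = "shoreline"),
    geometry = list(type = "MultiLineString", coordinates = shore))
  jsonlite::write_json(list(type = "FeatureCollection",
                            config_hash = hash, features = feats),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
}

#' Write a raster matrix to CSV
#'
#' Row-major cell-centre convention, one CSV row per raster row (`ix`),
#' with a `# config_hash:` header comment.
#'
#' @param mat numeric matrix.
#' @param path output file.
#' @param hash configuration hash.
#' @export
writeRasterCSV <- function(mat, path, hash = "") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  utils::write.table(mat, con, row.names = FALSE, col.names = FALSE,
                     sep = ",")
}

#' Serialize a fit result to a versioned JSON sidecar
#'
#' Records the covariate specification, coefficients, smoothing
#' parameters, Tweedie power, scale, AIC, deviance explained and the AIC
#' definition.
#'
#' @param fitres a [FitResult-class].
#' @param path output file.
#' @param hash configuration hash.
#' @export
writeFitJSON <- function(fitres, path, hash = "") {
  fit <- fitres@fit
  jsonlite::write_json(list(
    format_version = 1L, config_hash = hash,
    covariates = fitres@spec@covariates,
    smooth_terms = fitres@spec@smoothTerms,
    parametric_terms = fitres@spec@parametricTerms,
    coefficients = as.list(stats::coef(fit)),
    smoothing_parameters = as.list(fit$sp),
    tweedie_power = fitres@power, scale = fitres@scale,
    aic = fitres@aic, aic_definition = fitres@aicDefinition,
    deviance_explained_pct = fitres@devExpl, reml = fitres@reml,
    n = fitres@n, edf = fitres@edf), path,
    auto_unbox = TRUE, digits = NA)
}
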