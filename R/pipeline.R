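#' @include synthetic.R
NULL

#' Assemble a titration series from loose spectra
#'
#' Orders a list of [Spectrum-class] objects by their `ligandM` metadata
#' and wraps them in a [TitrationSeries-class]; protein concentration and
#' temperature are taken from the (consistent) spectrum metadata.
#'
#' @param spectra list of [Spectrum-class] objects with `ligandM` set,
#'   e.g. from [readSpectra()].
#' @return a [TitrationSeries-class].
#' @export
asTitrationSeries <- function(spectra) {
  lig <- vapply(spectra, ligandConc, numeric(1))
  if (anyNA(lig))
    stop("every spectrum needs ligand_M metadata to form a titration series")
  o <- order(lig)
  prot <- unique(vapply(spectra, proteinConc, numeric(1)))
  temp <- unique(vapply(spectra, function(s) s@temperatureK, numeric(1)))
  if (length(prot[is.finite(prot)]) > 1L)
    stop("spectra carry conflicting protein concentrations")
  if (length(temp[is.finite(temp)]) > 1L)
    stop("spectra carry conflicting temperatures")
  TitrationSeries(spectra[o], lig[o],
                  proteinM = if (any(is.finite(prot))) prot[is.finite(prot)]
                  else NA_real_,
                  temperatureK = if (any(is.finite(temp)))
                    temp[is.finite(temp)] else NA_real_)
}

#' Inner-filter correct every spectrum of a titration series
#'
#' Applies [innerFilterCorrect()] step by step. Absorbance comes either
#' from measured total-sample spectra (one per step) or, when
#' `absorbance = NULL`, from the ligand Beer-Lambert band built with
#' [ligandAbsorbanceSpectrum()] at each step's total ligand concentration.
#'
#' @param series a [TitrationSeries-class] of emission spectra.
#' @param absorbance optional list of absorbance [Spectrum-class], aligned
#'   with the titration steps.
#' @param ... band parameters passed to [ligandAbsorbanceSpectrum()].
#' @return the corrected [TitrationSeries-class].
#' @export
correctTitration <- function(series, absorbance = NULL, ...) {
  stopifnot(is(series, "TitrationSeries"))
  if (!is.null(absorbance) && length(absorbance) != length(series@spectra))
    stop("need one absorbance spectrum per titration step")
  grid <- series@spectra[[1L]]@wavelength
  exc <- series@spectra[[1L]]@excitationNm
  absGrid <- seq(floor(min(grid, exc)) - 5, ceiling(max(grid)) + 5, by = 1)
  corrected <- lapply(seq_along(series@spectra), function(i) {
    ab <- if (is.null(absorbance))
      ligandAbsorbanceSpectrum(series@ligandM[i], gridNm = absGrid, ...)
    else absorbance[[i]]
    innerFilterCorrect(series@spectra[[i]], ab)
  })
  TitrationSeries(corrected, series@ligandM, proteinM = series@proteinM,
                  temperatureK = series@temperatureK)
}

.CONFIG_KEYS <- list(
  quench = c("spectraFiles", "absorbanceFiles", "tau0Ns", "mode", "read",
             "outputDir", "seed"),
  thermo = c("kaTable", "temperatures", "Ka", "KaSE", "outputDir", "seed"),
  idf = c("spectraFiles", "absorbanceFiles", "mode", "read", "nLevels",
          "maxClasses", "njPolicy", "r2Min", "outputDir", "seed"))

#' Validate a pipeline run configuration
#'
#' A run configuration is a named list (or path to a YAML file holding
#' one). Validation checks the keys against the schema of the requested
#' pipeline — unknown keys are rejected — and the presence of required
#' inputs.
#'
#' @param config named list or YAML file path.
#' @param pipeline one of `"quench"`, `"thermo"`, `"idf"`.
#' @return the validated config list, invisibly enriched with defaults.
#' @export
validateRunConfig <- function(config,
                              pipeline = c("quench", "thermo", "idf")) {
  pipeline <- match.arg(pipeline)
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop(sprintf("config file not found: '%s'",
                                           config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config) ||
      (length(config) && (is.null(names(config)) ||
                          any(!nzchar(names(config))))))
    stop("config must be a named list or a YAML file of one")
  allowed <- .CONFIG_KEYS[[pipeline]]
  unknown <- setdiff(names(config), allowed)
  if (length(unknown))
    stop(sprintf("unknown config key(s) for pipeline '%s': %s",
                 pipeline, paste(unknown, collapse = ", ")))
  req <- switch(pipeline,
                quench = "spectraFiles",
                thermo = character(0),
                idf = "spectraFiles")
  missing <- setdiff(req, names(config))
  if (length(missing))
    stop(sprintf("missing required config key(s): %s",
                 paste(missing, collapse = ", ")))
  if (pipeline == "thermo" && is.null(config$kaTable) &&
      (is.null(config$temperatures) || is.null(config$Ka)))
    stop("thermo pipeline needs either 'kaTable' or 'temperatures' + 'Ka'")
  if (!is.null(config$spectraFiles)) {
    absent <- !file.exists(config$spectraFiles)
    if (any(absent))
      stop(sprintf("input file(s) not found: %s",
                   paste(config$spectraFiles[absent], collapse = ", ")))
  }
  if (is.null(config$outputDir)) config$outputDir <- tempdir()
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$mode)) config$mode <- "intensity"
  invisible(config)
}

.provenance <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config[order(names(config))], tmp)
  list(configMd5 = unname(tools::md5sum(tmp)),
       seed = config$seed,
       package = "quenchfit",
       version = as.character(utils::packageVersion("quenchfit")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

.writeReport <- function(report, dir, stem) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonPath <- file.path(dir, paste0(stem, ".json"))
  jsonlite::write_json(report, jsonPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  jsonPath
}

.loadCorrectedSeries <- function(config) {
  lapply(seq_along(config$spectraFiles), function(i) {
    series <- asTitrationSeries(readSpectra(config$spectraFiles[i]))
    if (all(vapply(series@spectra, isCorrected, logical(1))))
      return(series)
    absorbance <- NULL
    if (!is.null(config$absorbanceFiles))
      absorbance <- readSpectra(config$absorbanceFiles[i])
    correctTitration(series, absorbance)
  })
}

#' Run the quenching pipeline
#'
#' Reads titration spectra (one file per temperature), applies the
#' whole-spectrum inner-filter correction (unless the file is flagged
#' corrected), builds quenching curves in both intensity and area modes,
#' and fits Stern-Volmer (with \eqn{k_q} when `tau0Ns` is given) and the
#' double-log binding model per temperature. Results are written as a
#' delimited table plus a JSON summary with a provenance block.
#'
#' @param config named list or YAML path; keys: `spectraFiles` (required),
#'   `absorbanceFiles`, `tau0Ns` (ns), `read`, `outputDir`, `seed`.
#' @return a list with `report` (data.frame, one row per temperature and
#'   mode), `files` (paths written) and `provenance`.
#' @export
runQuenching <- function(config) {
  config <- validateRunConfig(config, "quench")
  seriesList <- .loadCorrectedSeries(config)
  tau0 <- if (!is.null(config$tau0Ns)) config$tau0Ns * 1e-9 else NA_real_
  rows <- list()
  for (series in seriesList) {
    for (mode in c("intensity", "area")) {
      crv <- buildCurve(series, mode = mode)
      sv <- sternVolmerFit(crv, tau0 = tau0)
      bl <- doubleLogFit(crv)
      rows[[length(rows) + 1L]] <- data.frame(
        temperature_K = series@temperatureK, mode = mode,
        Ksv_per_M = sv@Ksv, Ksv_SE = sv@KsvSE, Ksv_r2 = sv@r2,
        kq_per_M_s = sv@kq,
        Ka_per_M = bl@Ka, Ka_SE = bl@KaSE,
        n_sites = bl@nSites, n_SE = bl@nSitesSE)
    }
  }
  report <- do.call(rbind, rows)
  prov <- .provenance(config)
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(config$outputDir, "quenching_report.csv")
  utils::write.csv(report, csv, row.names = FALSE)
  json <- .writeReport(list(report = report, provenance = prov),
                       config$outputDir, "quenching_report")
  list(report = report, files = c(csv, json), provenance = prov)
}

#' Run the thermodynamics pipeline
#'
#' Consumes a table of binding constants by temperature (CSV with columns
#' `temperature_K`, `Ka`, optional `KaSE`, or inline vectors) and produces
#' the Van't Hoff decomposition: \eqn{\Delta H}, \eqn{\Delta S}, and per
#' temperature \eqn{\Delta G} (both regression and direct forms) and
#' \eqn{T\Delta S}.
#'
#' @param config named list or YAML path; keys: `kaTable` or
#'   `temperatures` + `Ka` (+ `KaSE`), `outputDir`, `seed`.
#' @return a list with `thermo` (the [ThermoResult-class]), `report`
#'   (data.frame), `files`, `provenance`.
#' @export
runThermo <- function(config) {
  config <- validateRunConfig(config, "thermo")
  if (!is.null(config$kaTable)) {
    tab <- utils::read.csv(config$kaTable)
    if (!all(c("temperature_K", "Ka") %in% names(tab)))
      stop("kaTable needs columns temperature_K, Ka")
    temps <- tab$temperature_K; Ka <- tab$Ka
    KaSE <- if ("KaSE" %in% names(tab)) tab$KaSE else NULL
  } else {
    temps <- config$temperatures; Ka <- config$Ka; KaSE <- config$KaSE
  }
  th <- vantHoffFit(temps, Ka, KaSE = KaSE)
  report <- data.frame(
    temperature_K = th@temperatures,
    deltaG_kJ_mol = th@deltaG,
    deltaG_direct_kJ_mol = th@deltaGdirect,
    deltaH_kJ_mol = th@deltaH, deltaH_SE = th@deltaHSE,
    deltaS_J_mol_K = th@deltaS, deltaS_SE = th@deltaSSE,
    TdeltaS_kJ_mol = th@TdeltaS)
  prov <- .provenance(config)
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(config$outputDir, "thermo_report.csv")
  utils::write.csv(report, csv, row.names = FALSE)
  json <- .writeReport(list(report = report, provenance = prov),
                       config$outputDir, "thermo_report")
  list(thermo = th, report = report, files = c(csv, json),
       provenance = prov)
}

#' Run the IDF pipeline
#'
#' Reads two or more titrations at distinct protein concentrations,
#' corrects them, matches constant-quench levels ([matchLevels()]), and
#' runs the Scatchard diagnostic and the multi-class Hill fit on the
#' resulting binding density curve. Writes the levels table, plot-ready
#' (free ligand, binding density) and Scatchard point sets, and a JSON
#' summary with provenance.
#'
#' @param config named list or YAML path; keys: `spectraFiles` (>= 2,
#'   required), `absorbanceFiles`, `mode`, `read`, `nLevels`,
#'   `maxClasses`, `njPolicy`, `r2Min`, `outputDir`, `seed`.
#' @return a list with `levels` ([IDFLevels-class]), `curve`
#'   ([BindingDensityCurve-class]), `scatchard` ([ScatchardResult-class]),
#'   `hill` ([HillModel-class]), `files`, `provenance`.
#' @export
runIDF <- function(config) {
  config <- validateRunConfig(config, "idf")
  if (length(config$spectraFiles) < 2L)
    stop("IDF needs titrations at >= 2 protein concentrations")
  seriesList <- .loadCorrectedSeries(config)
  mode <- if (identical(config$mode, "intensity")) "intensity" else "area"
  lv <- matchLevels(seriesList,
                    nLevels = if (is.null(config$nLevels)) 20
                    else config$nLevels,
                    mode = mode, read = config$read,
                    r2Min = if (is.null(config$r2Min)) 0.95
                    else config$r2Min)
  crv <- bindingDensityCurve(lv)
  sc <- scatchard(crv)
  hill <- hillFit(crv,
                  maxClasses = if (is.null(config$maxClasses)) 3
                  else config$maxClasses,
                  njPolicy = if (is.null(config$njPolicy)) "fixed"
                  else config$njPolicy)
  prov <- .provenance(config)
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  levelsCsv <- file.path(config$outputDir, "idf_levels.csv")
  utils::write.csv(lv@levels, levelsCsv, row.names = FALSE)
  pointsCsv <- file.path(config$outputDir, "binding_density.csv")
  utils::write.csv(data.frame(freeLigand_M = crv@freeLigandM,
                              sumNu = crv@sumNu,
                              scatchard_y = sc@ratio),
                   pointsCsv, row.names = FALSE)
  json <- .writeReport(list(
    scatchardVerdict = sc@verdict,
    nClasses = hill@nClasses,
    classes = hill@classes,
    modelScan = hill@scan,
    provenance = prov), config$outputDir, "idf_report")
  list(levels = lv, curve = crv, scatchard = sc, hill = hill,
       files = c(levelsCsv, pointsCsv, json), provenance = prov)
}
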