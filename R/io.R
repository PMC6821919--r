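#' @include spectrum-methods.R
NULL

# Parse "# key: value" header lines; returns named character vector.
# Errors name the offending line number.
.parseHeader <- function(lines, path) {
  keys <- character(); vals <- character()
  for (i in seq_along(lines)) {
    body <- sub("^#\\s*", "", lines[i])
    if (!grepl("^[A-Za-z_][A-Za-z0-9_]*\\s*:", body))
      stop(sprintf("malformed metadata header at line %d of '%s': '%s'",
                   i, path, lines[i]), call. = FALSE)
    key <- sub("\\s*:.*$", "", body)
    val <- sub("^[^:]*:\\s*", "", body)
    keys <- c(keys, key); vals <- c(vals, val)
  }
  stats::setNames(vals, keys)
}

.headerNum <- function(meta, key, n = 1L) {
  if (!key %in% names(meta)) return(rep(NA_real_, n))
  v <- suppressWarnings(as.numeric(strsplit(meta[[key]], ",")[[1]]))
  if (anyNA(v))
    stop(sprintf("metadata key '%s' is not numeric: '%s'", key, meta[[key]]),
         call. = FALSE)
  if (length(v) == 1L) rep(v, n)
  else if (length(v) == n) v
  else stop(sprintf(
    "metadata key '%s' has %d values but the file holds %d series",
    key, length(v), n), call. = FALSE)
}

#' Read spectra from a delimited text file
#'
#' The file format is long-format delimited text (comma or tab, detected
#' automatically, UTF-8) with a metadata header of `# key: value` lines
#' followed by a column-name row and columns `series_id`, `wavelength_nm`,
#' `value`. Recognised metadata keys: `kind` (required), `excitation_nm`
#' (required for emission), `delta_nm` (required for synchronous),
#' `temperature_K`, `protein_M`, `ligand_M`, `corrected` (true/false).
#' A numeric key may carry either a single value applying to every series or
#' a comma-separated list with one value per series in order of first
#' appearance (the usual case for `ligand_M` in a titration file).
#'
#' @param path path to the file.
#' @return a list of [Spectrum-class] objects, one per `series_id`, in order
#'   of first appearance.
#' @seealso [writeSpectra()] for the inverse.
#' @export
readSpectra <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  lines <- readLines(path, encoding = "UTF-8")
  isHead <- grepl("^#", lines)
  firstData <- which(!isHead & nzchar(trimws(lines)))
  if (!length(firstData)) stop(sprintf("no data rows in '%s'", path))
  if (any(isHead[seq(firstData[1], length(lines))]))
    stop(sprintf("metadata header lines must precede the data in '%s'", path))
  meta <- .parseHeader(lines[isHead], path)
  if (!"kind" %in% names(meta))
    stop(sprintf("missing required metadata key 'kind' in '%s'", path))
  kind <- trimws(meta[["kind"]])

  nameRow <- lines[firstData[1]]
  delim <- if (grepl("\t", nameRow)) "\t" else ","
  df <- utils::read.table(text = lines[firstData], sep = delim, header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("series_id", "wavelength_nm", "value")
  if (!all(need %in% names(df)))
    stop(sprintf("'%s' must have columns %s", path,
                 paste(need, collapse = ", ")))
  ids <- unique(df$series_id)
  n <- length(ids)
  exc <- .headerNum(meta, "excitation_nm", n)
  dlt <- .headerNum(meta, "delta_nm", n)
  tk <- .headerNum(meta, "temperature_K", n)
  pm <- .headerNum(meta, "protein_M", n)
  lm <- .headerNum(meta, "ligand_M", n)
  corr <- if ("corrected" %in% names(meta))
    tolower(trimws(meta[["corrected"]])) %in% c("true", "yes", "1")
  else FALSE
  if (kind == "emission" && anyNA(exc))
    stop(sprintf("kind 'emission' requires metadata key 'excitation_nm' in '%s'",
                 path))
  if (kind == "synchronous" && anyNA(dlt))
    stop(sprintf("kind 'synchronous' requires metadata key 'delta_nm' in '%s'",
                 path))
  out <- vector("list", n)
  names(out) <- ids
  for (i in seq_len(n)) {
    sub <- df[df$series_id == ids[i], , drop = FALSE]
    out[[i]] <- Spectrum(kind, sub$wavelength_nm, sub$value,
                         excitationNm = exc[i], deltaNm = dlt[i],
                         temperatureK = tk[i], proteinM = pm[i],
                         ligandM = lm[i], ifeCorrected = corr)
  }
  out
}

#' Write spectra to a delimited text file
#'
#' Inverse of [readSpectra()]: all spectra must share kind; per-spectrum
#' numeric metadata are written as comma-separated lists when they differ.
#'
#' @param spectra a [Spectrum-class] or list of them.
#' @param path output path.
#' @param delim field delimiter, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
writeSpectra <- function(spectra, path, delim = ",") {
  if (is(spectra, "Spectrum")) spectra <- list(spectra)
  stopifnot(length(spectra) >= 1L, delim %in% c(",", "\t"))
  kinds <- vapply(spectra, spectrumKind, character(1))
  if (length(unique(kinds)) != 1L)
    stop("all spectra written to one file must share the same kind")
  ids <- names(spectra)
  if (is.null(ids) || any(!nzchar(ids)))
    ids <- sprintf("s%02d", seq_along(spectra))
  fmtKey <- function(key, vals) {
    vals <- vals[is.finite(vals)]
    if (!length(vals)) return(NULL)
    sprintf("# %s: %s", key, paste(format(vals, digits = 15, trim = TRUE),
                                   collapse = ","))
  }
  collect <- function(get) {
    v <- vapply(spectra, get, numeric(1))
    if (all(!is.finite(v))) numeric(0)
    else if (length(unique(v[is.finite(v)])) == 1L && !anyNA(v)) v[1L]
    else v
  }
  hdr <- c(sprintf("# kind: %s", kinds[1L]),
           fmtKey("excitation_nm", collect(function(s) s@excitationNm)),
           fmtKey("delta_nm", collect(function(s) s@deltaNm)),
           fmtKey("temperature_K", collect(function(s) s@temperatureK)),
           fmtKey("protein_M", collect(function(s) s@proteinM)),
           fmtKey("ligand_M", collect(function(s) s@ligandM)),
           sprintf("# corrected: %s",
                   tolower(all(vapply(spectra, isCorrected, logical(1))))))
  rows <- do.call(rbind, lapply(seq_along(spectra), function(i)
    data.frame(series_id = ids[i],
               wavelength_nm = wavelengths(spectra[[i]]),
               value = intensities(spectra[[i]]))))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(rows, con, sep = delim, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a TCSPC decay trace
#'
#' Two-column delimited text (`time_ns`, `counts`) with a `# key: value`
#' metadata header (`excitation_nm`, `emission_nm`, `ligand_M`).
#'
#' @param path path to the file.
#' @return a [DecayTrace-class] object.
#' @export
readDecay <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path))
  lines <- readLines(path, encoding = "UTF-8")
  isHead <- grepl("^#", lines)
  meta <- .parseHeader(lines[isHead], path)
  dataLines <- lines[!isHead & nzchar(trimws(lines))]
  delim <- if (grepl("\t", dataLines[1])) "\t" else ","
  df <- utils::read.table(text = dataLines, sep = delim, header = TRUE)
  if (!all(c("time_ns", "counts") %in% names(df)))
    stop(sprintf("'%s' must have columns time_ns, counts", path))
  DecayTrace(df$time_ns, df$counts,
             excitationNm = .headerNum(meta, "excitation_nm"),
             emissionNm = .headerNum(meta, "emission_nm"),
             ligandM = .headerNum(meta, "ligand_M"))
}

#' Write a TCSPC decay trace
#'
#' @param trace a [DecayTrace-class] object.
#' @param path output path.
#' @param delim field delimiter, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
writeDecay <- function(trace, path, delim = ",") {
  stopifnot(is(trace, "DecayTrace"))
  hdr <- c(
    if (is.finite(trace@excitationNm))
      sprintf("# excitation_nm: %g", trace@excitationNm),
    if (is.finite(trace@emissionNm))
      sprintf("# emission_nm: %g", trace@emissionNm),
    if (is.finite(trace@ligandM))
      sprintf("# ligand_M: %s", format(trace@ligandM, digits = 15)))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (length(hdr)) writeLines(hdr, con)
  utils::write.table(data.frame(time_ns = trace@timeNs,
                                counts = trace@counts),
                     con, sep = delim, row.names = FALSE, quote = FALSE)
  invisible(path)
}
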