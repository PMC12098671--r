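#' @include panels.R
NULL

pkgVersionString <- function() {
  as.character(utils::packageVersion("syncfluor"))
}

# every file we write starts with provenance comments; readers skip and
# re-parse them as key: value metadata
writeHeader <- function(con, meta = list()) {
  writeLines(sprintf("# syncfluor %s", pkgVersionString()), con)
  keep <- c("axis_kind", "delta_lambda_nm", "sample_id", "units", "seed")
  for (k in keep) {
    if (!is.null(meta[[k]]) && !is.na(meta[[k]]))
      writeLines(sprintf("# %s: %s", k, format(meta[[k]])), con)
  }
}

readHeaderMeta <- function(path) {
  lines <- readLines(path, n = 20L)
  lines <- lines[startsWith(lines, "#")]
  meta <- list()
  for (ln in grep(":", lines, value = TRUE)) {
    body <- sub("^#\\s*", "", ln)
    key <- sub(":.*$", "", body)
    val <- trimws(sub("^[^:]*:", "", body))
    meta[[trimws(key)]] <- val
  }
  meta
}

#' Read a 1-D spectrum from CSV
#'
#' Expects two numeric columns, \code{wavelength_nm,intensity}, optionally
#' preceded by \code{#} metadata comments. Rows are sorted into ascending
#' wavelength order (with a warning if the file was shuffled); duplicate
#' wavelengths are an error; a non-uniform axis is linearly resampled onto
#' a uniform grid of the same span with a warning.
#'
#' @param path CSV file.
#' @return a \linkS4class{FluorSpectrum} (or \linkS4class{SyncSpectrum}
#'   when the header carries a delta-lambda).
#' @seealso [writeSpectrumCsv()]
#' @export
readSpectrumCsv <- function(path) {
  if (!file.exists(path)) dataError("spectrum file not found: %s", path)
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", check.names = FALSE),
    error = function(e) dataError("cannot parse '%s': %s", path, conditionMessage(e)))
  need <- c("wavelength_nm", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    dataError("'%s' is missing required column(s): %s", path,
              paste(miss, collapse = ", "))
  w <- df$wavelength_nm; y <- df$intensity
  if (!is.numeric(w) || !is.numeric(y) || anyNA(w) || anyNA(y))
    dataError("'%s' contains non-numeric cells in wavelength_nm/intensity", path)
  if (anyDuplicated(w)) {
    dup <- w[duplicated(w)][1]
    dataError("'%s' contains duplicate wavelength rows (e.g. %g nm)", path, dup)
  }
  if (is.unsorted(w)) {
    warning(sprintf("'%s': wavelengths were not ascending; rows sorted", path))
    o <- order(w); w <- w[o]; y <- y[o]
  }
  d <- diff(w)
  if (length(d) && (max(d) - min(d)) > 1e-6 * mean(d)) {
    warning(sprintf("'%s': non-uniform wavelength axis; linearly resampled", path))
    wu <- seq(w[1], w[length(w)], length.out = length(w))
    y <- stats::approx(w, y, xout = wu)$y
    w <- wu
  }
  meta <- readHeaderMeta(path)
  dl <- suppressWarnings(as.numeric(meta$delta_lambda_nm))
  kind <- if (!is.null(meta$axis_kind)) meta$axis_kind else "emission"
  keep <- meta[setdiff(names(meta), c("axis_kind", "delta_lambda_nm"))]
  if (identical(kind, "synchronous-emission")) {
    if (length(dl) == 0L || is.na(dl))
      dataError("'%s' claims a synchronous axis but carries no delta_lambda_nm", path)
    new("SyncSpectrum", axisKind = kind, wavelengths = w, intensities = y,
        deltaLambda = dl, meta = keep)
  } else {
    new("FluorSpectrum", axisKind = kind, wavelengths = w, intensities = y,
        meta = keep)
  }
}

#' Write a 1-D spectrum to CSV
#'
#' @param spectrum a \linkS4class{FluorSpectrum}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeSpectrumCsv <- function(spectrum, path) {
  stopifnot(is(spectrum, "FluorSpectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  meta <- spectrum@meta
  meta$axis_kind <- spectrum@axisKind
  if (is(spectrum, "SyncSpectrum"))
    meta$delta_lambda_nm <- spectrum@deltaLambda
  writeHeader(con, meta)
  utils::write.csv(
    data.frame(wavelength_nm = spectrum@wavelengths,
               intensity = spectrum@intensities),
    con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an EEM from long-form CSV
#'
#' Expects columns \code{ex_nm,em_nm,intensity} covering a complete
#' rectangular grid; a ragged grid is an error reporting how many cells
#' are missing.
#'
#' @param path CSV file.
#' @return an \linkS4class{EEM}.
#' @seealso [writeEEMCsv()]
#' @export
readEEMCsv <- function(path) {
  if (!file.exists(path)) dataError("EEM file not found: %s", path)
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("ex_nm", "em_nm", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    dataError("'%s' is missing required column(s): %s", path,
              paste(miss, collapse = ", "))
  ex <- sort(unique(df$ex_nm))
  em <- sort(unique(df$em_nm))
  expected <- length(ex) * length(em)
  if (nrow(df) != expected || anyDuplicated(df[c("ex_nm", "em_nm")])) {
    missing <- expected - nrow(unique(df[c("ex_nm", "em_nm")]))
    dataError("'%s' is not a complete rectangular grid: %d missing grid cell%s",
              path, missing, if (missing == 1) "" else "s")
  }
  m <- matrix(NA_real_, length(ex), length(em))
  m[cbind(match(df$ex_nm, ex), match(df$em_nm, em))] <- df$intensity
  new("EEM", exWavelengths = ex, emWavelengths = em, intensities = m,
      meta = list(source = path))
}

#' Write an EEM to long-form CSV
#'
#' @param eem an \linkS4class{EEM}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeEEMCsv <- function(eem, path) {
  stopifnot(is(eem, "EEM"))
  con <- file(path, "w")
  on.exit(close(con))
  writeHeader(con, list(seed = eem@meta$seed))
  df <- data.frame(
    ex_nm = rep(eem@exWavelengths, times = length(eem@emWavelengths)),
    em_nm = rep(eem@emWavelengths, each = length(eem@exWavelengths)),
    intensity = as.vector(eem@intensities))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a sample sheet
#'
#' Long-form CSV with columns \code{sample_id,analyte,conc_ug_per_ml}.
#'
#' @param sheet data.frame as produced by [panelSheet()].
#' @param path CSV file.
#' @return the path ([writeSampleSheet()]) or the data.frame
#'   ([readSampleSheet()]).
#' @export
writeSampleSheet <- function(sheet, path) {
  need <- c("sample_id", "analyte", "conc_ug_per_ml")
  if (!all(need %in% names(sheet)))
    dataError("sample sheet needs columns: %s", paste(need, collapse = ", "))
  con <- file(path, "w")
  on.exit(close(con))
  writeHeader(con)
  utils::write.csv(sheet[need], con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSampleSheet
#' @export
readSampleSheet <- function(path) {
  if (!file.exists(path)) dataError("sample sheet not found: %s", path)
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("sample_id", "analyte", "conc_ug_per_ml")
  miss <- setdiff(need, names(df))
  if (length(miss))
    dataError("'%s' is missing required column(s): %s", path,
              paste(miss, collapse = ", "))
  df
}
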