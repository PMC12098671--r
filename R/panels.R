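#' @include simulate.R
NULL

#' Simulate a calibration panel
#'
#' One EEM per concentration level and replicate for a single analyte,
#' optionally in the presence of a fixed co-analyte concentration.
#' Per-sample seeds are derived deterministically from the master seed with
#' [childSeed()], so an identical call reproduces the panel bit for bit.
#'
#' @param analyte name of the analyte being calibrated; must match one of
#'   \code{models}.
#' @param levels concentration levels, ug/mL; non-empty.
#' @param coAnalyte optional named numeric of length 1, e.g.
#'   \code{c(ASP = 4)}, held constant across the panel.
#' @param replicates replicate EEMs per level, >= 1.
#' @param noise a \linkS4class{NoiseModel}.
#' @param seed master seed.
#' @param models named list of \linkS4class{Fluorophore}.
#' @param background flat background, AFU.
#' @param exWavelengths,emWavelengths scan axes.
#' @return list of \linkS4class{EEM}; each EEM's \code{meta$sample} holds
#'   the analyte, level, replicate id and per-sample seed.
#' @seealso [panelSheet()], [mixturePanel()]
#' @export
calibrationPanel <- function(analyte, levels, coAnalyte = NULL,
                             replicates = 3, noise = defaultNoise(),
                             seed = 1, models = defaultModels(),
                             background = 2,
                             exWavelengths = wavelengthGrid(220, 500, 1),
                             emWavelengths = wavelengthGrid(250, 600, 1)) {
  if (length(levels) == 0L) dataError("calibration level list must not be empty")
  if (replicates < 1L) dataError("'replicates' must be >= 1")
  if (!analyte %in% names(models))
    dataError("analyte '%s' not found among models (%s)", analyte,
              paste(names(models), collapse = ", "))
  out <- vector("list", length(levels) * replicates)
  k <- 0L
  for (li in seq_along(levels)) {
    for (r in seq_len(replicates)) {
      k <- k + 1L
      conc <- stats::setNames(numeric(length(models)), names(models))
      conc[analyte] <- levels[li]
      if (!is.null(coAnalyte)) {
        if (is.null(names(coAnalyte)) || !all(names(coAnalyte) %in% names(models)))
          dataError("'coAnalyte' must be a named concentration matching a model")
        conc[names(coAnalyte)] <- coAnalyte
      }
      s <- childSeed(seed, k)
      eem <- simulateEEM(models, conc, exWavelengths, emWavelengths,
                         noise = noise, background = background, seed = s)
      eem@meta$sample <- list(analyte = analyte, level = levels[li],
                              replicate = r, seed = s)
      out[[k]] <- eem
    }
  }
  out
}

#' The laboratory-mixture concentration series
#'
#' The fixed-ratio (1:3.75, ATO:ASP) binary mixture series used by the
#' selectivity study: ATO at 0.5-2.5 ug/mL against 3.75x as much ASP.
#'
#' @return data.frame with columns \code{ASP} and \code{ATO} (ug/mL).
#' @export
defaultMixturePairs <- function() {
  ato <- c(0.5, 1, 1.5, 2, 2.5)
  data.frame(ASP = 3.75 * ato, ATO = ato)
}

#' Simulate a panel of binary mixtures
#'
#' @param pairs data.frame (or 2-column matrix) of concentrations in ug/mL;
#'   column names must match \code{models} names. Defaults to the 1:3.75
#'   ratio series of [defaultMixturePairs()].
#' @param noise a \linkS4class{NoiseModel}.
#' @param seed master seed.
#' @param models,background,exWavelengths,emWavelengths as in
#'   [calibrationPanel()].
#' @return list of \linkS4class{EEM} with truth recorded in
#'   \code{meta$concentrations}.
#' @export
mixturePanel <- function(pairs = defaultMixturePairs(),
                         noise = defaultNoise(), seed = 1,
                         models = defaultModels(), background = 2,
                         exWavelengths = wavelengthGrid(220, 500, 1),
                         emWavelengths = wavelengthGrid(250, 600, 1)) {
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) == 0L) dataError("'pairs' must contain at least one mixture")
  if (!all(names(pairs) %in% names(models)))
    dataError("mixture columns (%s) must match model names (%s)",
              paste(names(pairs), collapse = ", "),
              paste(names(models), collapse = ", "))
  lapply(seq_len(nrow(pairs)), function(i) {
    conc <- stats::setNames(numeric(length(models)), names(models))
    conc[names(pairs)] <- as.numeric(pairs[i, ])
    s <- childSeed(seed, i)
    eem <- simulateEEM(models, conc, exWavelengths, emWavelengths,
                       noise = noise, background = background, seed = s)
    eem@meta$sample <- list(mixture = i, seed = s)
    eem
  })
}

#' Sample sheet of a simulated panel
#'
#' @param panel list of \linkS4class{EEM} from [calibrationPanel()] or
#'   [mixturePanel()].
#' @return long-form data.frame with columns \code{sample_id},
#'   \code{analyte}, \code{conc_ug_per_ml}.
#' @export
panelSheet <- function(panel) {
  rows <- lapply(seq_along(panel), function(i) {
    cc <- panel[[i]]@meta$concentrations
    data.frame(sample_id = i, analyte = names(cc),
               conc_ug_per_ml = as.numeric(cc))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
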