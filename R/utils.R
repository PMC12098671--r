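#' @include AllClasses.R
NULL

# condition helpers: data errors (bad inputs/files) vs numeric failures,
# so the CLI can map them onto distinct exit codes.
dataError <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("syncfluor_data_error", "syncfluorError")))
}

numericError <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("syncfluor_numeric_error", "syncfluorError")))
}

# evaluate expr under a local RNG state; the caller's stream is untouched
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Derive a reproducible child seed
#'
#' Deterministically maps a master seed and a stage/sample index onto a
#' 31-bit child seed, so panels and pipeline stages are reproducible from a
#' single master seed yet use distinct streams.
#'
#' @param seed master seed (integer).
#' @param k stage or sample index (integer >= 0).
#' @return an integer in \code{[1, 2^31 - 2]}.
#' @export
childSeed <- function(seed, k) {
  s <- (abs(as.double(seed)) %% 2147483647) + 1
  as.integer(((s * 48271) %% 2147483647 + as.double(k) * 99991) %% 2147483629 + 1)
}

#' Uniform wavelength grid
#'
#' @param start,stop grid endpoints in nm, \code{stop > start}.
#' @param step grid step in nm, > 0.
#' @return strictly ascending, uniformly spaced numeric axis in nm.
#' @examples
#' wavelengthGrid(250, 600, 1)
#' @export
wavelengthGrid <- function(start, stop, step = 1) {
  if (!is.finite(start) || !is.finite(stop) || !is.finite(step))
    dataError("wavelength grid endpoints and step must be finite")
  if (step <= 0) dataError("grid step must be > 0 (got %g)", step)
  if (stop <= start) dataError("grid stop (%g) must exceed start (%g)", stop, start)
  seq(start, stop, by = step)
}

gridStep <- function(w) (w[length(w)] - w[1]) / (length(w) - 1)

# linear interpolation on a uniform grid; x must lie within [w1, wn]
interpUniform <- function(w, y, x) {
  step <- gridStep(w)
  pos <- (x - w[1]) / step
  i <- pmin(pmax(floor(pos), 0), length(w) - 2)
  f <- pos - i
  y[i + 1] * (1 - f) + y[i + 2] * f
}

fmtRange <- function(lo, hi) sprintf("[%g, %g] nm", lo, hi)

# round-half-up at a given number of decimals (report style); R's round()
# is banker's rounding which never matches printed assay tables
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
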