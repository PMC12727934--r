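#' Frequency band definition
#'
#' A band is a named open-below, closed-above frequency interval in Hz.
#' The half-open convention `(lo, hi]` makes adjacent bands partition their
#' union exactly, so relative powers over a tiling band set sum to 1.
#'
#' @param name Band label, e.g. `"delta"`.
#' @param lo,hi Band edges in Hz, `0 < lo < hi`.
#' @return A `band_definition` object (named list with `name`, `lo`, `hi`).
#' @examples
#' band_definition("alpha", 8, 13)
#' @export
band_definition <- function(name, lo, hi) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(lo) || !is.numeric(hi) || length(lo) != 1L ||
      length(hi) != 1L || !is.finite(lo) || !is.finite(hi)) {
    stop("band edges must be finite numbers", call. = FALSE)
  }
  if (lo <= 0 || hi <= lo) {
    stop("invalid band: need 0 < lo < hi, got [", lo, ", ", hi, "]",
         call. = FALSE)
  }
  structure(list(name = name, lo = lo, hi = hi), class = "band_definition")
}

#' Canonical EEG analysis bands
#'
#' The four bands used throughout the analysis: delta (1-4 Hz), theta
#' (4-8 Hz), alpha (8-13 Hz) and beta (13-20 Hz).  They tile (1, 20] Hz,
#' the default total range for relative power.
#'
#' @return Named list of [band_definition()] objects in canonical order.
#' @export
canonical_bands <- function() {
  list(
    delta = band_definition("delta", 1, 4),
    theta = band_definition("theta", 4, 8),
    alpha = band_definition("alpha", 8, 13),
    beta  = band_definition("beta", 13, 20)
  )
}

#' @export
print.band_definition <- function(x, ...) {
  cat(sprintf("<band> %s: (%g, %g] Hz\n", x$name, x$lo, x$hi))
  invisible(x)
}

canonical_band_order <- function() c("delta", "theta", "alpha", "beta")

as_band_list <- function(bands) {
  if (inherits(bands, "band_definition")) return(stats::setNames(list(bands), bands$name))
  stopifnot(is.list(bands), length(bands) > 0L)
  ok <- vapply(bands, inherits, logical(1), "band_definition")
  if (!all(ok)) stop("`bands` must be band_definition objects", call. = FALSE)
  stats::setNames(bands, vapply(bands, `[[`, character(1), "name"))
}
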