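#' Spectrum container
#'
#' An axis/amplitude pair with a kind tag. Field-swept spectra carry a field
#' axis in mT; ENDOR and ELDOR-NMR spectra carry a frequency-offset axis in
#' MHz (offset from q times the nuclear Larmor frequency).
#'
#' @param axis Strictly monotone numeric axis (mT or MHz depending on
#'   `kind`).
#' @param amplitude Numeric amplitudes, same length as `axis`, finite.
#' @param kind One of `"fieldsweep"`, `"endor"`, `"eldor_sq"`, `"eldor_dq"`.
#' @param meta Optional named list of metadata (settings snapshot, axis
#'   convention note, linewidths used, ...).
#' @return Object of class `spectrum_1d`.
#' @export
spectrum_1d <- function(axis, amplitude,
                        kind = c("fieldsweep", "endor", "eldor_sq",
                                 "eldor_dq"),
                        meta = list()) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(axis), is.numeric(amplitude),
            length(axis) == length(amplitude), length(axis) >= 2L,
            is.list(meta))
  if (!all(is.finite(amplitude))) stop("amplitudes must be finite",
                                       call. = FALSE)
  d <- diff(axis)
  if (!(all(d > 0) || all(d < 0))) {
    stop("axis must be strictly monotone", call. = FALSE)
  }
  if (d[1] < 0) {  # store ascending
    axis <- rev(axis); amplitude <- rev(amplitude)
  }
  structure(list(axis = axis, amplitude = amplitude, kind = kind,
                 meta = meta),
            class = "spectrum_1d")
}

#' @export
print.spectrum_1d <- function(x, ...) {
  unit <- if (x$kind == "fieldsweep") "mT" else "MHz"
  cat(sprintf("<spectrum_1d> %s: %d points, axis %.4g to %.4g %s\n",
              x$kind, length(x$axis), min(x$axis), max(x$axis), unit))
  invisible(x)
}

#' @export
plot.spectrum_1d <- function(x, ...) {
  unit <- if (x$kind == "fieldsweep") "Field (mT)" else "Offset (MHz)"
  graphics::plot(x$axis, x$amplitude, type = "l", xlab = unit,
                 ylab = "Amplitude (a.u.)", main = x$kind, ...)
  invisible(x)
}
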