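#' Construct a spectrum
#'
#' A spectrum is a tibble with columns `wavelength_nm` and `value`, carrying
#' the signal kind (`"absorbance"`, `"emission"` or `"extinction"`) and a free
#' text label as attributes. Wavelengths are in nm and must be strictly
#' increasing; extinction coefficients (M^-1 cm^-1) must be non-negative.
#'
#' @param wavelength_nm Numeric vector of wavelengths (nm), strictly
#'   increasing, length >= 2.
#' @param value Numeric vector of the same length: absorbance (AU), emission
#'   intensity (AU) or molar extinction (M^-1 cm^-1).
#' @param kind One of `"absorbance"`, `"emission"`, `"extinction"`.
#' @param label Free-text description.
#'
#' @return A tibble of class `spectrum` with columns `wavelength_nm`, `value`.
#' @export
#' @examples
#' s <- spectrum(290:400, dnorm(290:400, 334, 25), kind = "emission")
#' band_area(s, 290, 400)
spectrum <- function(wavelength_nm, value,
                     kind = c("absorbance", "emission", "extinction"),
                     label = "") {
  kind <- match.arg(kind)
  if (!is.numeric(wavelength_nm) || !is.numeric(value)) {
    stop_invalid("wavelengths and values must be numeric")
  }
  if (length(wavelength_nm) < 2L) {
    stop_invalid("a spectrum needs at least 2 wavelengths")
  }
  if (length(wavelength_nm) != length(value)) {
    stop_invalid("wavelengths and values must have equal length")
  }
  if (anyNA(wavelength_nm) || anyNA(value)) {
    stop_invalid("spectrum contains missing values")
  }
  bad <- which(diff(wavelength_nm) <= 0)
  if (length(bad)) {
    stop_invalid(sprintf(
      "wavelengths must be strictly increasing (violated at row %d: %g >= %g)",
      bad[1] + 1L, wavelength_nm[bad[1]], wavelength_nm[bad[1] + 1L]
    ))
  }
  if (kind == "extinction" && any(value < 0)) {
    stop_invalid("extinction coefficients must be >= 0")
  }
  out <- tibble::tibble(wavelength_nm = as.numeric(wavelength_nm),
                        value = as.numeric(value))
  class(out) <- c("spectrum", class(out))
  attr(out, "kind") <- kind
  attr(out, "label") <- label
  out
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %s%s, %d points, %g-%g nm>\n",
              attr(x, "kind"),
              if (nzchar(attr(x, "label"))) paste0(" '", attr(x, "label"), "'") else "",
              nrow(x), min(x$wavelength_nm), max(x$wavelength_nm)))
  NextMethod()
}

spectrum_kind <- function(s) attr(s, "kind") %||% "absorbance"

as_spectrum <- function(x, kind = "absorbance", label = "") {
  if (inherits(x, "spectrum")) return(x)
  spectrum(x[[1]], x[[2]], kind = kind, label = label)
}

#' Read or write a spectrum file
#'
#' Spectrum files are two-column delimited text (comma or tab separated) with
#' a header line `wavelength_nm,<value_name>`; lines starting with `#` are
#' comments. Non-monotonic wavelength columns are rejected with a diagnostic
#' naming the offending row. Values are written with 10 significant digits so
#' a read/write/read round trip is exact in decimal text.
#'
#' @param path File path.
#' @param kind Signal kind to stamp on the returned spectrum.
#' @param label Label for the returned spectrum.
#'
#' @return `read_spectrum()` a `spectrum`; `write_spectrum()` the path,
#'   invisibly.
#' @export
read_spectrum <- function(path, kind = c("absorbance", "emission", "extinction"),
                          label = basename(path)) {
  kind <- match.arg(kind)
  tab <- read_delim_table(path, n_cols = 2L)
  spectrum(tab[[1]], tab[[2]], kind = kind, label = label)
}

#' @rdname read_spectrum
#' @param s A `spectrum`.
#' @param value_name Column name used for the value column in the header.
#' @param comments Character vector of comment lines to prepend (written with
#'   a leading `#`).
#' @export
write_spectrum <- function(s, path, value_name = spectrum_kind(s),
                           comments = character()) {
  s <- as_spectrum(s)
  write_delim_table(
    data.frame(wavelength_nm = s$wavelength_nm, value = s$value),
    path, col_names = c("wavelength_nm", value_name), comments = comments
  )
}

#' Correct fluorescence intensities for the inner filter effect
#'
#' An absorbing ligand attenuates both the excitation beam and the emitted
#' light; the measured intensity is corrected multiplicatively as
#' \deqn{I_{cor} = I_{obs} \cdot 10^{(A_{ex} + A_{em})/2}}
#' where `A_ex` and `A_em` are the absorbance differences caused by ligand
#' addition at the excitation wavelength and at the emission wavelength(s).
#'
#' @param i_obs Measured intensity: a non-negative numeric vector or a
#'   `spectrum` of kind `"emission"`.
#' @param a_ex Absorbance difference at the excitation wavelength (AU).
#' @param a_em Absorbance difference at the emission wavelength(s): a scalar,
#'   or a vector matching `i_obs` element-wise.
#'
#' @return Corrected intensity with the same shape as `i_obs`.
#' @export
#' @examples
#' inner_filter_correct(100, a_ex = 0.1, a_em = 0.1)
inner_filter_correct <- function(i_obs, a_ex, a_em) {
  is_spec <- inherits(i_obs, "spectrum")
  vals <- if (is_spec) i_obs$value else i_obs
  if (!all(is.finite(a_ex)) || !all(is.finite(a_em))) {
    stop_invalid("absorbance differences must be finite")
  }
  if (any(vals < 0)) stop_invalid("measured intensities must be >= 0")
  if (length(a_em) != 1L && length(a_em) != length(vals)) {
    stop_invalid("a_em must be scalar or match the intensity length")
  }
  cor <- vals * 10^((a_ex + a_em) / 2)
  if (is_spec) {
    spectrum(i_obs$wavelength_nm, cor, kind = spectrum_kind(i_obs),
             label = attr(i_obs, "label"))
  } else {
    cor
  }
}

#' Integrate a spectral band
#'
#' Trapezoidal integral of the spectrum over `[lo, hi]` on the native
#' wavelength grid. When `lo` or `hi` falls between grid points the endpoint
#' value is obtained by linear interpolation so the integration limits are
#' honoured exactly. The conventional window for the tryptophan emission band
#' is 290-400 nm.
#'
#' @param s A `spectrum` (or two-column data frame).
#' @param lo,hi Integration limits (nm), `lo < hi`; the interval must overlap
#'   the spectrum's wavelength range.
#'
#' @return The band area (value x nm).
#' @export
band_area <- function(s, lo, hi) {
  s <- as_spectrum(s)
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi) {
    stop_invalid("need finite integration limits with lo < hi")
  }
  w <- s$wavelength_nm
  a <- max(lo, w[1])
  b <- min(hi, w[length(w)])
  if (a >= b) {
    stop_range(sprintf("[%g, %g] nm does not overlap the spectrum range [%g, %g] nm",
                       lo, hi, w[1], w[length(w)]))
  }
  inside <- w > a & w < b
  grid <- c(a, w[inside], b)
  vals <- stats::approx(w, s$value, xout = grid)$y
  pracma::trapz(grid, vals)
}

#' Smoothed second derivative of a spectrum
#'
#' Sliding local quadratic least-squares (Savitzky-Golay-type) second
#' derivative with respect to wavelength. The fit is performed on the actual
#' wavelength values, so unevenly spaced grids are handled correctly. The
#' output grid equals the input grid; near the edges the window slides
#' one-sided so every point gets a full `window`-point fit.
#'
#' Useful for partition titrations where the second-derivative amplitude at a
#' fixed wavelength replaces the raw absorbance change, suppressing residual
#' scattering baselines.
#'
#' @param s A `spectrum`.
#' @param window Odd number of points in the local fit, >= 5 and <= the
#'   series length. Default 7.
#'
#' @return A `spectrum` of the same kind holding d2(value)/d(wavelength)^2.
#' @export
second_derivative <- function(s, window = 7L) {
  s <- as_spectrum(s)
  n <- nrow(s)
  window <- as.integer(window)
  if (window %% 2L == 0L) stop_param("window must be odd")
  if (window < 5L) stop_param("window must be >= 5")
  if (window > n) stop_param(sprintf("window (%d) exceeds series length (%d)", window, n))
  half <- (window - 1L) %/% 2L
  w <- s$wavelength_nm
  y <- s$value
  d2 <- numeric(n)
  for (i in seq_len(n)) {
    lo <- min(max(1L, i - half), n - window + 1L)
    idx <- lo:(lo + window - 1L)
    x <- w[idx] - w[i]
    X <- cbind(1, x, x^2)
    beta <- qr.coef(qr(X), y[idx])
    d2[i] <- 2 * beta[3]
  }
  out <- spectrum(w, d2, kind = spectrum_kind(s),
                  label = paste0("d2/dl2 ", attr(s, "label")))
  out
}

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation onto `grid`. Extrapolation outside the source range is
#' refused: the band shape beyond the measured range is unknown.
#'
#' @param s A `spectrum`.
#' @param grid Strictly ascending wavelengths (nm) inside the source range.
#'
#' @return A `spectrum` on `grid`.
#' @export
resample <- function(s, grid) {
  s <- as_spectrum(s)
  if (any(diff(grid) <= 0)) stop_invalid("target grid must be strictly ascending")
  w <- s$wavelength_nm
  if (min(grid) < w[1] || max(grid) > w[length(w)]) {
    stop_range(sprintf(
      "target grid [%g, %g] nm extends beyond the source range [%g, %g] nm; extrapolation is not supported",
      min(grid), max(grid), w[1], w[length(w)]
    ))
  }
  vals <- stats::approx(w, s$value, xout = grid)$y
  spectrum(grid, vals, kind = spectrum_kind(s), label = attr(s, "label"))
}

#' Plot a spectrum
#'
#' @param object A `spectrum`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spectrum <- function(object, ...) {
  ylab <- switch(spectrum_kind(object),
                 absorbance = "Absorbance (AU)",
                 emission = "Emission intensity (AU)",
                 extinction = expression(epsilon ~ (M^-1 ~ cm^-1)))
  ggplot2::ggplot(object, ggplot2::aes(.data$wavelength_nm, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Wavelength (nm)", y = ylab, title = attr(object, "label"))
}
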