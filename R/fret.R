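#' Spectral overlap integral
#'
#' Computes the donor-acceptor overlap integral
#' \deqn{J = \int I(\lambda)\,\varepsilon(\lambda)\,\lambda^4\, d\lambda}
#' where I is the donor emission spectrum area-normalized to unit integral
#' over its recorded range (on the nm grid) and epsilon the acceptor molar
#' extinction (M^-1 cm^-1). Both spectra are resampled onto the intersection
#' of their wavelength ranges at the finer of the two native grid steps, and
#' the integral is evaluated by the trapezoid rule.
#'
#' @param donor Donor emission `spectrum`.
#' @param acceptor Acceptor extinction `spectrum` (M^-1 cm^-1), values >= 0.
#' @param normalize_range Wavelength range (nm) over which the donor is
#'   normalized to unit area; defaults to the donor's full recorded range.
#'
#' @return J in M^-1 cm^-1 nm^4. Disjoint spectra give 0 with a warning.
#' @export
overlap_integral <- function(donor, acceptor, normalize_range = NULL) {
  donor <- as_spectrum(donor, kind = "emission")
  acceptor <- as_spectrum(acceptor, kind = "extinction")
  if (any(acceptor$value < 0)) stop_invalid("acceptor extinction must be >= 0")
  lo <- max(min(donor$wavelength_nm), min(acceptor$wavelength_nm))
  hi <- min(max(donor$wavelength_nm), max(acceptor$wavelength_nm))
  if (lo >= hi) {
    warning("donor and acceptor spectra do not overlap; J = 0")
    return(structure(0, no_overlap = TRUE))
  }
  nr <- normalize_range %||% range(donor$wavelength_nm)
  area <- band_area(donor, nr[1], nr[2])
  if (area <= 0) stop_invalid("donor emission has non-positive area; cannot normalize")
  step <- min(stats::median(diff(donor$wavelength_nm)),
              stats::median(diff(acceptor$wavelength_nm)))
  grid <- seq(lo, hi, by = step)
  if (grid[length(grid)] < hi) grid <- c(grid, hi)
  id <- stats::approx(donor$wavelength_nm, donor$value, xout = grid)$y / area
  ea <- stats::approx(acceptor$wavelength_nm, acceptor$value, xout = grid)$y
  pracma::trapz(grid, id * ea * grid^4)
}

#' Forster radius
#'
#' The critical transfer distance at which resonance energy transfer is 50%
#' efficient:
#' \deqn{R_0 = 0.2108\,[\kappa^2\, \Phi_F\, n^{-4}\, J]^{1/6}\ \mathrm{\AA}}
#' with J in M^-1 cm^-1 nm^4. Defaults: kappa2 = 2/3 (dynamic random
#' orientation) and n = 1.425 (aqueous protein solution).
#'
#' @param J Overlap integral (M^-1 cm^-1 nm^4), > 0.
#' @param quantum_yield Donor quantum yield in the absence of acceptor,
#'   in (0, 1].
#' @param refractive_index Medium refractive index, >= 1.
#' @param kappa2 Orientation factor, in (0, 4].
#'
#' @return R0 in Angstrom.
#' @export
#' @examples
#' forster_radius(6.68e13, quantum_yield = 0.1)
forster_radius <- function(J, quantum_yield, refractive_index = 1.425,
                           kappa2 = 2 / 3) {
  if (any(J <= 0) || any(quantum_yield <= 0) || any(refractive_index <= 0) ||
      any(kappa2 <= 0)) {
    stop_param("all Forster-radius inputs must be > 0")
  }
  if (any(quantum_yield > 1)) stop_param("quantum yield must be <= 1")
  if (any(refractive_index < 1)) stop_param("refractive index must be >= 1")
  if (any(kappa2 > 4)) stop_param("kappa^2 must be <= 4")
  0.2108 * (kappa2 * quantum_yield * refractive_index^-4 * J)^(1 / 6)
}

#' Maximum distance at which energy transfer is significant
#'
#' Energy transfer is only significant at donor-acceptor distances
#' r < 1.5 R0; this bound is used to place an upper limit on the ligand
#' distance from the donor tryptophan.
#'
#' @param R0 Forster radius (Angstrom), >= 0.
#' @return 1.5 * R0 (Angstrom).
#' @export
max_significant_distance <- function(R0) {
  if (any(R0 < 0)) stop_param("R0 must be >= 0")
  1.5 * R0
}

#' Full FRET geometry analysis
#'
#' Convenience wrapper: overlap integral, Forster radius, and the
#' significance bound, returned as a one-row tibble `J, R0_A, r_max_A`.
#'
#' @inheritParams overlap_integral
#' @inheritParams forster_radius
#' @return A one-row tibble with columns `J`, `R0_A`, `r_max_A`.
#' @export
fret_analysis <- function(donor, acceptor, quantum_yield,
                          refractive_index = 1.425, kappa2 = 2 / 3,
                          normalize_range = NULL) {
  J <- overlap_integral(donor, acceptor, normalize_range = normalize_range)
  R0 <- forster_radius(J, quantum_yield, refractive_index, kappa2)
  tibble::tibble(J = as.numeric(J), R0_A = R0,
                 r_max_A = max_significant_distance(R0))
}
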