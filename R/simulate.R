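#' Noise specification for the synthetic-data generators
#'
#' Additive Gaussian noise with standard deviation `sigma` expressed relative
#' to the signal's dynamic range. `kind = "none"` yields deterministic
#' output; for Gaussian noise a `seed` is mandatory so that identical
#' (seed, parameters) always produce bit-identical data.
#'
#' @param kind `"none"` or `"gaussian"`.
#' @param sigma Relative noise standard deviation, >= 0.
#' @param seed Integer seed (required when `kind = "gaussian"`).
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(kind = c("none", "gaussian"), sigma = 0, seed = NULL) {
  kind <- match.arg(kind)
  if (sigma < 0) stop_param("sigma must be >= 0")
  if (kind == "gaussian" && is.null(seed)) {
    stop_param("gaussian noise requires an explicit seed")
  }
  structure(list(kind = kind, sigma = sigma, seed = seed), class = "noise_spec")
}

# Adds noise scaled by `scale` (the model's dynamic range) to `x`.
apply_noise <- function(x, noise, scale) {
  if (is.null(noise) || noise$kind == "none" || noise$sigma == 0) return(x)
  withr::with_seed(noise$seed, x + stats::rnorm(length(x), 0, noise$sigma * scale))
}

gaussian_band <- function(grid, peak, width, amplitude) {
  amplitude * exp(-(grid - peak)^2 / (2 * width^2))
}

#' Simulate a protein emission spectrum
#'
#' A Gaussian emission band, by default emulating the tryptophan emission of
#' serum albumin: maximum at 334 nm, recorded 290-400 nm. Gaussian band
#' shapes keep closed-form areas available for oracle checks; real emission
#' bands are asymmetric.
#'
#' @param peak_nm Band maximum (nm).
#' @param width_nm Gaussian sigma (nm), > 0.
#' @param amplitude Peak intensity (AU).
#' @param grid Wavelength grid (nm), ascending.
#' @param noise A [noise_spec()].
#' @return An emission `spectrum`; for `noise = none` the argmax is at
#'   `peak_nm`.
#' @export
sim_emission_spectrum <- function(peak_nm = 334, width_nm = 25, amplitude = 1,
                                  grid = seq(290, 400, by = 1),
                                  noise = noise_spec("none")) {
  if (any(diff(grid) <= 0)) stop_invalid("grid must be strictly ascending")
  if (width_nm <= 0) stop_param("width must be > 0")
  v <- gaussian_band(grid, peak_nm, width_nm, amplitude)
  v <- apply_noise(v, noise, amplitude)
  spectrum(grid, v, kind = "emission", label = "simulated emission")
}

#' Simulate a drug absorbance spectrum with hydrolytic conversion
#'
#' Emulates a prodrug whose intact form shows a major band at 329 nm and a
#' minor band at 258 nm, converting on hydrolysis to a product with a single
#' band at 265 nm. The spectrum is the mixture
#' (1 - f) x intact + f x product for degraded fraction f.
#'
#' @param fraction_degraded Degraded fraction f in [0, 1].
#' @param grid Wavelength grid (nm).
#' @param amplitude Peak absorbance of the intact major band (AU).
#' @param noise A [noise_spec()].
#' @return An absorbance `spectrum`. At f = 0 the argmax is 329 nm; at f = 1
#'   the band peaks at 265 nm.
#' @export
sim_drug_absorbance <- function(fraction_degraded = 0,
                                grid = seq(240, 400, by = 1),
                                amplitude = 1,
                                noise = noise_spec("none")) {
  if (any(diff(grid) <= 0)) stop_invalid("grid must be strictly ascending")
  if (fraction_degraded < 0 || fraction_degraded > 1) {
    stop_param("fraction_degraded must be in [0, 1]")
  }
  f <- fraction_degraded
  intact <- gaussian_band(grid, 329, 14, amplitude) +
    gaussian_band(grid, 258, 9, 0.55 * amplitude)
  product <- gaussian_band(grid, 265, 12, 0.9 * amplitude)
  v <- (1 - f) * intact + f * product
  v <- apply_noise(v, noise, amplitude)
  spectrum(grid, v, kind = "absorbance", label = sprintf("simulated drug, f=%g", f))
}

#' Simulate a quenching titration
#'
#' Forward models matching the two analyses of quenching data:
#' `"stern_volmer"` generates I = I0 / (1 + K_SV [Q]);
#' `"isotherm"` generates I = I0 - (I0 - Ic) [L] / (1/K_a + [L]).
#' Noiseless output is exactly inverted by [fit_stern_volmer()] or
#' [fit_binding_isotherm()] respectively.
#'
#' @param model `"stern_volmer"` or `"isotherm"`.
#' @param params Named list: `K_SV`, `I0` for the Stern-Volmer model;
#'   `K_a`, `I0`, `Ic` for the isotherm.
#' @param conc_grid Quencher/ligand concentrations (M), must include 0.
#' @param temperature_C Stamped on the titration.
#' @param noise A [noise_spec()] (sigma relative to I0).
#' @return A `quench_titration`.
#' @export
sim_quench_titration <- function(model = c("stern_volmer", "isotherm"),
                                 params, conc_grid, temperature_C = 25,
                                 noise = noise_spec("none")) {
  model <- match.arg(model)
  if (!any(conc_grid == 0)) stop_invalid("conc_grid must include the zero point")
  I0 <- params$I0 %||% 1
  if (model == "stern_volmer") {
    if (is.null(params$K_SV)) stop_param("stern_volmer model needs K_SV")
    I <- I0 / (1 + params$K_SV * conc_grid)
  } else {
    if (is.null(params$K_a)) stop_param("isotherm model needs K_a")
    Ic <- params$Ic %||% 0
    I <- I0 - (I0 - Ic) * conc_grid / (1 / params$K_a + conc_grid)
  }
  I <- apply_noise(I, noise, I0)
  I <- pmax(I, 1e-9 * I0)
  quench_titration(conc_grid, I, temperature_C = temperature_C)
}

#' Simulate a partition titration
#'
#' Forward model dA = dA_max [lipid] / (1/(K_p gamma) + [lipid]) plus
#' optional noise (sigma relative to `delta_A_max`).
#'
#' @param K_p Partition coefficient (dimensionless).
#' @param gamma Lipid molar volume (M^-1). Default 0.9.
#' @param delta_A_max Saturation absorbance change (AU).
#' @param lipid_grid Lipid concentrations (M), >= 0.
#' @param noise A [noise_spec()].
#' @return A `partition_titration`.
#' @export
sim_partition_titration <- function(K_p, gamma = 0.9, delta_A_max = 0.05,
                                    lipid_grid = seq(0, 3e-3, length.out = 8),
                                    noise = noise_spec("none")) {
  if (any(lipid_grid < 0)) stop_invalid("lipid concentrations must be >= 0")
  dA <- delta_A_max * lipid_grid / (1 / (K_p * gamma) + lipid_grid)
  dA <- apply_noise(dA, noise, delta_A_max)
  partition_titration(lipid_grid, dA, gamma = gamma)
}

#' Simulate an anisotropy-vs-temperature series
#'
#' The sigmoidal anisotropy drop of a membrane probe through the lipid phase
#' transition, encoded as polarized intensity pairs: the target anisotropy
#' r(T) = r_high + (r_low - r_high)/(1 + exp((T - T_m)/width)) is inverted to
#' (I_VV, I_VH) at the given G factor and unit total intensity, and noise is
#' added on the intensities. Defaults emulate DPH in DMPC vesicles: plateaus
#' 0.339 (gel) and 0.092 (fluid) around a 23 deg C transition.
#'
#' @param T_grid Temperatures (deg C).
#' @param r_low,r_high Gel- and fluid-phase anisotropy plateaus, in (-0.5, 1).
#' @param T_m Transition midpoint (deg C).
#' @param width Transition width (deg C), > 0.
#' @param G Instrument G factor.
#' @param noise A [noise_spec()] (sigma relative to the mean intensity).
#' @return A tibble with columns `temperature_C`, `I_VV`, `I_VH`, `I_HV`,
#'   `I_HH` (the horizontal-excitation pair encodes G).
#' @export
sim_anisotropy_series <- function(T_grid = seq(10, 37, length.out = 15),
                                  r_low = 0.339, r_high = 0.092, T_m = 23,
                                  width = 1, G = 1,
                                  noise = noise_spec("none")) {
  if (any(c(r_low, r_high) <= -0.5) || any(c(r_low, r_high) >= 1)) {
    stop_invalid("anisotropy plateaus must be in (-0.5, 1)")
  }
  if (width <= 0) stop_param("width must be > 0")
  r <- r_high + (r_low - r_high) / (1 + exp((T_grid - T_m) / width))
  ints <- anisotropy_to_intensities(r, G = G)
  n <- length(T_grid)
  I <- apply_noise(c(ints$I_VV, ints$I_VH), noise, mean(ints$I_VV))
  tibble::tibble(
    temperature_C = T_grid,
    I_VV = pmax(I[seq_len(n)], 0),
    I_VH = pmax(I[n + seq_len(n)], 0),
    I_HV = rep(G, n),
    I_HH = rep(1, n)
  )
}

#' Simulate a first-order decay series
#'
#' A(t) = A_inf + (A0 - A_inf) exp(-k t) plus optional noise (sigma relative
#' to A0).
#'
#' @param k Rate constant (h^-1), >= 0.
#' @param A0 Initial signal (AU).
#' @param A_inf Terminal plateau (AU).
#' @param t_grid Time points (h), ascending from 0.
#' @param noise A [noise_spec()].
#' @return A `decay_series`.
#' @export
sim_decay_series <- function(k, A0 = 1, A_inf = 0,
                             t_grid = seq(0, 8, length.out = 20),
                             noise = noise_spec("none")) {
  if (k < 0) stop_param("k must be >= 0")
  v <- A_inf + (A0 - A_inf) * exp(-k * t_grid)
  v <- apply_noise(v, noise, A0)
  decay_series(t_grid, pmax(v, 1e-9 * A0))
}
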