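#' Build a quenching titration table
#'
#' A quenching titration records the integrated (inner-filter-corrected)
#' emission intensity of a protein at increasing quencher concentrations.
#' The zero-quencher point defines I0 unless `i0` is supplied.
#'
#' @param conc_M Quencher concentration per point (M), non-negative.
#' @param intensity Integrated emission intensity (AU), > 0.
#' @param temperature_C Sample temperature (deg C).
#' @param i0 Optional explicit unquenched intensity; defaults to the
#'   intensity at `conc_M == 0`.
#'
#' @return A tibble of class `quench_titration` with columns `conc_M`,
#'   `intensity`, and attributes `temperature_K`, `i0`.
#' @export
quench_titration <- function(conc_M, intensity, temperature_C = 25, i0 = NULL) {
  if (length(conc_M) != length(intensity)) {
    stop_invalid("conc_M and intensity must have equal length")
  }
  if (any(conc_M < 0)) stop_invalid("quencher concentrations must be >= 0")
  if (any(intensity <= 0)) stop_invalid("intensities must be > 0")
  if (is.null(i0)) {
    zi <- which(conc_M == 0)
    if (!length(zi)) {
      stop_invalid("titration has no zero-quencher point; supply i0 explicitly")
    }
    i0 <- mean(intensity[zi])
  }
  out <- tibble::tibble(conc_M = as.numeric(conc_M),
                        intensity = as.numeric(intensity))
  out <- dplyr::arrange(out, .data$conc_M)
  class(out) <- c("quench_titration", class(out))
  attr(out, "temperature_K") <- celsius_to_kelvin(temperature_C)
  attr(out, "i0") <- i0
  out
}

#' Read a titration file
#'
#' Delimited text with header `conc_M,intensity`; optional metadata comments
#' such as `# temperature_C: 25`.
#'
#' @param path File path.
#' @return A `quench_titration`.
#' @export
read_quench_titration <- function(path) {
  tab <- read_delim_table(path, n_cols = 2L)
  meta <- attr(tab, "meta")
  temp <- as.numeric(meta[["temperature_C"]] %||% 25)
  quench_titration(tab[[1]], tab[[2]], temperature_C = temp)
}

#' Stern-Volmer analysis of a quenching titration
#'
#' Fits the linear Stern-Volmer relation I0/I = 1 + K_SV [Q] by ordinary
#' least squares of I0/I against quencher concentration. The slope is the
#' Stern-Volmer constant K_SV (M^-1); the intercept is reported and should be
#' close to 1 for well-behaved data.
#'
#' @param t A `quench_titration` (or a data frame with `conc_M`, `intensity`).
#'
#' @return An object of class `sv_fit` with elements `K_SV`, `K_SV_se`,
#'   `intercept`, `r_squared`, `non_quenching` (TRUE when the fitted slope is
#'   negative) and `data` (the ratios used).
#' @export
#' @examples
#' t <- sim_quench_titration("stern_volmer", list(K_SV = 4837, I0 = 1),
#'                           conc_grid = seq(0, 55e-6, length.out = 12))
#' fit_stern_volmer(t)
fit_stern_volmer <- function(t) {
  t <- as_quench(t)
  if (length(unique(t$conc_M)) < 3L) {
    stop_invalid("Stern-Volmer fit needs >= 3 distinct quencher concentrations")
  }
  i0 <- attr(t, "i0")
  ratio <- i0 / t$intensity
  fit <- stats::lm(ratio ~ conc_M, data = data.frame(conc_M = t$conc_M, ratio = ratio))
  co <- summary(fit)$coefficients
  slope <- unname(co["conc_M", "Estimate"])
  out <- structure(list(
    K_SV = slope,
    K_SV_se = unname(co["conc_M", "Std. Error"]),
    intercept = unname(co["(Intercept)", "Estimate"]),
    r_squared = summary(fit)$r.squared,
    non_quenching = slope < 0,
    temperature_K = attr(t, "temperature_K"),
    data = tibble::tibble(conc_M = t$conc_M, ratio = ratio,
                          fitted = stats::fitted(fit))
  ), class = "sv_fit")
  out
}

#' @export
print.sv_fit <- function(x, ...) {
  cat(sprintf("Stern-Volmer fit: K_SV = %.4g +/- %.2g M^-1 (intercept %.4g, R^2 %.4f)%s\n",
              x$K_SV, x$K_SV_se, x$intercept, x$r_squared,
              if (x$non_quenching) " [flagged: non-quenching]" else ""))
  invisible(x)
}

#' Bimolecular quenching rate constant
#'
#' k_q = K_SV / tau0, where tau0 is the unquenched fluorescence lifetime of
#' the fluorophore. For protein tryptophan an average integral lifetime of
#' 6.4 ns is conventional.
#'
#' @param K_SV Stern-Volmer constant (M^-1).
#' @param tau0_s Fluorophore lifetime (s), > 0. Default 6.4 ns.
#' @return k_q in M^-1 s^-1.
#' @export
bimolecular_rate_constant <- function(K_SV, tau0_s = 6.4e-9) {
  if (!is.finite(tau0_s) || tau0_s <= 0) stop_param("tau0 must be > 0")
  K_SV / tau0_s
}

#' Classify the quenching mechanism
#'
#' Quenching is classified as static (ground-state complex formation) when
#' the apparent bimolecular rate constant exceeds the maximum diffusion
#' collision rate of quenchers with a macromolecule, 2.0e10 M^-1 s^-1.
#' Values at or below the limit are compatible with dynamic (collisional)
#' quenching.
#'
#' @param k_q Bimolecular quenching rate constant (M^-1 s^-1), >= 0.
#' @param diffusion_limit Diffusion collision limit (M^-1 s^-1).
#' @return `"static"` or `"dynamic-compatible"`.
#' @export
classify_quenching <- function(k_q, diffusion_limit = 2.0e10) {
  if (any(k_q < 0)) stop_invalid("k_q must be >= 0")
  ifelse(k_q > diffusion_limit, "static", "dynamic-compatible")
}

#' Fit a 1:1 binding isotherm to quenching data
#'
#' Fits the saturation model
#' \deqn{\Delta I = I_0 - I = (I_0 - I_c)\frac{[L]}{1/K_a + [L]}}
#' by bounded nonlinear least squares, where `Ic` is the fluorescence of the
#' fully complexed protein. The model assumes a 1:1 complex and ligand in
#' excess over protein (no depletion of free ligand). I0 is taken from the
#' zero-ligand point unless carried on the titration; Ic is bounded to
#' [0, I0]. Initial guesses come from a double-reciprocal linearization and
#' the optimiser restarts from jittered guesses if needed.
#'
#' @param t A `quench_titration`.
#' @return An object of class `binding_fit` with `K_a`, `K_a_se`, `K_d`,
#'   `I0`, `Ic`, `Ic_se` and the fitted data.
#' @export
#' @examples
#' t <- sim_quench_titration("isotherm", list(K_a = 5103, I0 = 1, Ic = 0),
#'                           conc_grid = seq(0, 4e-4, length.out = 12))
#' fit_binding_isotherm(t)
fit_binding_isotherm <- function(t) {
  t <- as_quench(t)
  pos <- t$conc_M > 0
  if (length(unique(t$conc_M)) < 4L) {
    stop_invalid("isotherm fit needs >= 4 distinct ligand concentrations")
  }
  cr <- range(t$conc_M[pos])
  if (cr[2] / cr[1] < 5) {
    stop_invalid("ligand concentrations must span at least a factor of 5")
  }
  i0 <- attr(t, "i0")
  d <- tibble::tibble(conc = t$conc_M[pos],
                      dI = i0 - t$intensity[pos])
  # double-reciprocal linearization: 1/dI = 1/amp + 1/(amp*Ka) * 1/conc
  lin <- stats::lm(y ~ x, data = data.frame(x = 1 / d$conc, y = 1 / pmax(d$dI, 1e-12)))
  amp0 <- 1 / max(stats::coef(lin)[1], 1e-12)
  ka0 <- abs(stats::coef(lin)[1] / stats::coef(lin)[2])
  if (!is.finite(ka0) || ka0 <= 0) ka0 <- 1 / stats::median(d$conc)
  amp0 <- min(max(amp0, 1e-6 * i0), i0)
  start_fn <- function(j) {
    f <- if (j > 0) exp(stats::rnorm(2, 0, j)) else c(1, 1)
    list(K_a = ka0 * f[1], amp = amp0 * f[2])
  }
  fit <- fit_nls_restarts(
    dI ~ amp * conc / (1 / K_a + conc), data = d, start_fn = start_fn,
    lower = c(K_a = 1e-6, amp = 0), upper = c(K_a = 1e12, amp = i0)
  )
  co <- summary(fit)$coefficients
  ka <- unname(co["K_a", "Estimate"])
  amp <- unname(co["amp", "Estimate"])
  structure(list(
    K_a = ka,
    K_a_se = unname(co["K_a", "Std. Error"]),
    K_d = 1 / ka,
    I0 = i0,
    Ic = i0 - amp,
    Ic_se = unname(co["amp", "Std. Error"]),
    temperature_K = attr(t, "temperature_K"),
    data = tibble::tibble(conc_M = d$conc, delta_I = d$dI,
                          fitted = stats::fitted(fit))
  ), class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("1:1 binding fit: K_a = %.4g +/- %.2g M^-1 (K_d = %.3g M), Ic/I0 = %.3f\n",
              x$K_a, x$K_a_se, x$K_d, x$Ic / x$I0))
  invisible(x)
}

#' Dissociation constant from an association constant
#'
#' @param K_a Association constant (M^-1), > 0.
#' @return K_d = 1/K_a (M).
#' @export
dissociation_constant <- function(K_a) {
  if (any(!is.finite(K_a)) || any(K_a <= 0)) stop_param("K_a must be > 0")
  1 / K_a
}

#' Gibbs free energy of binding
#'
#' Delta G = -R T ln(K_a), with R = 8.3145 J mol^-1 K^-1.
#'
#' @param K_a Association constant (M^-1), > 0.
#' @param T_K Absolute temperature (K), > 0. Default 298.15 K (25 deg C).
#' @return Delta G in J mol^-1.
#' @export
gibbs_free_energy <- function(K_a, T_K = 298.15) {
  if (any(!is.finite(K_a)) || any(K_a <= 0)) stop_param("K_a must be > 0")
  if (any(!is.finite(T_K)) || any(T_K <= 0)) stop_param("temperature must be > 0 K")
  -R_GAS * T_K * log(K_a)
}

#' Van't Hoff thermodynamic parameters
#'
#' With exactly two temperatures the closed two-point form is used:
#' Delta H = -R ln(K2/K1) / (1/T2 - 1/T1); Delta S = (Delta H - Delta G(T2)) / T2,
#' with Delta G from [gibbs_free_energy()]. With three or more temperatures a
#' weighted linear regression of ln K against 1/T is fitted (slope = -dH/R,
#' intercept = dS/R), and Delta G is reported at the highest temperature.
#'
#' @param K_a Association constants (M^-1), one per temperature.
#' @param T_K Absolute temperatures (K), same length, all distinct.
#' @param weights Optional regression weights (>= 3 temperatures only).
#' @return A list of class `thermo_params`: `dG` (J/mol, at `T` K), `dH`
#'   (J/mol), `dS` (J/mol/K), `T` (K). Satisfies dG = dH - T dS.
#' @export
#' @examples
#' vant_hoff(c(2000, 4000), c(288.15, 298.15))
vant_hoff <- function(K_a, T_K, weights = NULL) {
  if (length(K_a) != length(T_K) || length(K_a) < 2L) {
    stop_invalid("need matching K_a and temperature vectors, length >= 2")
  }
  if (any(K_a <= 0) || any(T_K <= 0)) stop_param("K_a and T must be > 0")
  if (anyDuplicated(T_K)) stop_invalid("temperatures must be distinct")
  if (length(K_a) == 2L) {
    dH <- -R_GAS * log(K_a[2] / K_a[1]) / (1 / T_K[2] - 1 / T_K[1])
    Tref <- T_K[2]
    dG <- gibbs_free_energy(K_a[2], Tref)
  } else {
    d <- data.frame(x = 1 / T_K, y = log(K_a))
    fit <- stats::lm(y ~ x, data = d, weights = weights)
    dH <- -R_GAS * unname(stats::coef(fit)["x"])
    Tref <- max(T_K)
    dG <- -R_GAS * Tref * unname(stats::predict(fit, data.frame(x = 1 / Tref)))
  }
  dS <- (dH - dG) / Tref
  structure(list(dG = dG, dH = dH, dS = dS, T = Tref, R_gas = R_GAS),
            class = "thermo_params")
}

#' @export
print.thermo_params <- function(x, ...) {
  cat(sprintf("dG = %.4g J/mol at %.2f K; dH = %.4g J/mol; dS = %.4g J/mol/K\n",
              x$dG, x$T, x$dH, x$dS))
  invisible(x)
}

as_quench <- function(t) {
  if (inherits(t, "quench_titration")) return(t)
  if (!all(c("conc_M", "intensity") %in% names(t))) {
    stop_invalid("expected columns conc_M and intensity")
  }
  quench_titration(t$conc_M, t$intensity)
}
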