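#' Instrumental G factor
#'
#' G = I_HV / I_HH corrects for the transmissivity bias of the detection
#' system between vertically and horizontally polarized emission, measured
#' with horizontally polarized excitation.
#'
#' @param I_HV,I_HH Polarized intensities (AU); `I_HH > 0`.
#' @return G (dimensionless).
#' @export
g_factor <- function(I_HV, I_HH) {
  if (any(!is.finite(I_HH)) || any(I_HH <= 0)) stop_invalid("I_HH must be > 0")
  if (any(I_HV < 0)) stop_invalid("intensities must be >= 0")
  I_HV / I_HH
}

#' Steady-state fluorescence anisotropy
#'
#' \deqn{\langle r\rangle = \frac{I_{VV} - G I_{VH}}{I_{VV} + 2 G I_{VH}}}
#' from the vertically excited emission components. G defaults to 1 for
#' instruments that pre-correct the transmissivity bias.
#'
#' @param I_VV,I_VH Polarized intensities (AU), >= 0.
#' @param G Instrumental correction factor (see [g_factor()]).
#' @return Anisotropy, in [-0.5, 1].
#' @export
#' @examples
#' steady_state_anisotropy(2.539, 1)  # DPH in a gel-phase bilayer
steady_state_anisotropy <- function(I_VV, I_VH, G = 1) {
  if (any(I_VV < 0) || any(I_VH < 0)) stop_invalid("intensities must be >= 0")
  den <- I_VV + 2 * G * I_VH
  if (any(den <= 0)) stop_invalid("total intensity I_VV + 2 G I_VH must be > 0")
  (I_VV - G * I_VH) / den
}

# Inverse of the anisotropy relation at a given G: intensity pair with unit
# total intensity reproducing anisotropy r. Used by the simulator.
anisotropy_to_intensities <- function(r, G = 1, total = 1) {
  if (any(r <= -0.5) || any(r >= 1)) stop_invalid("anisotropy must be in (-0.5, 1)")
  # solve I_VV - G I_VH = r * (I_VV + 2 G I_VH) with I_VV + 2 G I_VH = total
  I_VV <- total * (1 + 2 * r) / 3
  I_VH <- total * (1 - r) / (3 * G)
  tibble::tibble(I_VV = I_VV, I_VH = I_VH)
}

#' Anisotropy-vs-temperature table from polarized intensities
#'
#' Converts a table with columns `temperature_C`, `I_VV`, `I_VH` (and
#' optionally `I_HV`, `I_HH`, from which a per-point G factor is computed)
#' into a tidy anisotropy curve. Without the horizontal-excitation
#' components G defaults to 1.
#'
#' @param readings Data frame of polarized readings.
#' @return A tibble with columns `temperature_C`, `r`, `G`.
#' @export
anisotropy_curve <- function(readings) {
  need <- c("temperature_C", "I_VV", "I_VH")
  if (!all(need %in% names(readings))) {
    stop_invalid("expected columns temperature_C, I_VV, I_VH")
  }
  G <- if (all(c("I_HV", "I_HH") %in% names(readings))) {
    g_factor(readings$I_HV, readings$I_HH)
  } else {
    rep(1, nrow(readings))
  }
  tibble::tibble(
    temperature_C = readings$temperature_C,
    r = steady_state_anisotropy(readings$I_VV, readings$I_VH, G),
    G = G
  )
}

#' Fit a thermotropic phase transition to an anisotropy curve
#'
#' Membrane probes such as DPH report the lipid gel-to-fluid transition as a
#' sigmoidal drop in steady-state anisotropy with temperature. The curve is
#' fitted with a four-parameter logistic
#' \deqn{r(T) = r_{high} + \frac{r_{low} - r_{high}}{1 + e^{(T - T_m)/w}}}
#' returning the midpoint temperature `T_m`, the gel (`r_low_T`) and fluid
#' (`r_high_T`) plateaus and the transition width `w` (deg C). A curve whose
#' fitted amplitude is below three residual standard deviations is rejected
#' as having no detectable transition.
#'
#' @param curve Data frame with columns `temperature_C` and `r` (>= 8
#'   temperatures spanning both plateaus).
#' @return An object of class `transition_fit` with `T_m`, `r_low_T`,
#'   `r_high_T`, `width`, standard errors and the fitted data.
#' @export
#' @examples
#' tc <- seq(10, 37, length.out = 15)
#' r <- 0.092 + (0.339 - 0.092) / (1 + exp((tc - 23) / 1))
#' fit_thermotropic_transition(data.frame(temperature_C = tc, r = r))
fit_thermotropic_transition <- function(curve) {
  if (!all(c("temperature_C", "r") %in% names(curve))) {
    stop_invalid("expected columns temperature_C and r")
  }
  d <- tibble::tibble(T = curve$temperature_C, r = curve$r)
  d <- dplyr::arrange(d, .data$T)
  if (length(unique(d$T)) < 8L) {
    stop_invalid("transition fit needs >= 8 temperatures")
  }
  rlo0 <- stats::median(utils::head(d$r, 3))
  rhi0 <- stats::median(utils::tail(d$r, 3))
  mid <- (rlo0 + rhi0) / 2
  tm0 <- d$T[which.min(abs(d$r - mid))]
  start_fn <- function(j) {
    jit <- if (j > 0) stats::rnorm(4, 0, j) else rep(0, 4)
    list(r_low = rlo0 * (1 + jit[1]), r_high = rhi0 * (1 + jit[2]),
         T_m = tm0 + jit[3] * 5, w = exp(jit[4]))
  }
  fit <- tryCatch(
    fit_nls_restarts(
      r ~ r_high + (r_low - r_high) / (1 + exp((T - T_m) / w)),
      data = d, start_fn = start_fn,
      lower = c(r_low = -0.5, r_high = -0.5, T_m = -Inf, w = 1e-3),
      upper = c(r_low = 1, r_high = 1, T_m = Inf, w = Inf)
    ),
    spectrobind_fit_failure = function(e) NULL
  )
  if (is.null(fit)) {
    # a sigmoid that cannot be fitted on a curve spanning both plateaus has
    # no detectable amplitude (e.g. constant anisotropy)
    stop_mismatch("no detectable transition: sigmoid fit is degenerate on this curve")
  }
  co <- summary(fit)$coefficients
  p <- co[, "Estimate"]
  sigma <- stats::sd(stats::resid(fit))
  if (abs(p["r_low"] - p["r_high"]) < 3 * sigma) {
    stop_mismatch("no detectable transition: fitted amplitude below 3x residual SD")
  }
  if (p["T_m"] < min(d$T) || p["T_m"] > max(d$T)) {
    # a midpoint outside the measured window means the curve shows no
    # transition within it
    stop_mismatch("no detectable transition: fitted midpoint lies outside the temperature range")
  }
  structure(list(
    T_m = unname(p["T_m"]), T_m_se = unname(co["T_m", "Std. Error"]),
    r_low_T = unname(p["r_low"]), r_high_T = unname(p["r_high"]),
    width = unname(p["w"]), width_se = unname(co["w", "Std. Error"]),
    model = "logistic in temperature",
    data = tibble::tibble(temperature_C = d$T, r = d$r,
                          fitted = stats::fitted(fit))
  ), class = "transition_fit")
}

#' @export
print.transition_fit <- function(x, ...) {
  cat(sprintf("Phase transition: T_m = %.2f +/- %.2f degC; plateaus %.3f -> %.3f; width %.2f degC\n",
              x$T_m, x$T_m_se, x$r_low_T, x$r_high_T, x$width))
  invisible(x)
}
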