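#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

one_term <- function(term, estimate, se) {
  tibble::tibble(term = term, estimate = estimate, std.error = se)
}

#' Tidy methods for spectrobind fit objects
#'
#' `tidy()` returns one row per fitted parameter with `term`, `estimate`,
#' `std.error`; `glance()` returns a one-row model summary.
#'
#' @param x A fit object (`sv_fit`, `binding_fit`, `partition_fit`,
#'   `transition_fit`, `decay_fit` or `thermo_params`).
#' @param ... Unused.
#' @return A tibble.
#' @name spectrobind-tidiers
NULL

#' @rdname spectrobind-tidiers
#' @export
tidy.sv_fit <- function(x, ...) {
  one_term(c("K_SV", "intercept"), c(x$K_SV, x$intercept), c(x$K_SV_se, NA_real_))
}

#' @rdname spectrobind-tidiers
#' @export
glance.sv_fit <- function(x, ...) {
  tibble::tibble(K_SV = x$K_SV, intercept = x$intercept,
                 r.squared = x$r_squared, non_quenching = x$non_quenching,
                 nobs = nrow(x$data))
}

#' @rdname spectrobind-tidiers
#' @export
tidy.binding_fit <- function(x, ...) {
  one_term(c("K_a", "Ic"), c(x$K_a, x$Ic), c(x$K_a_se, x$Ic_se))
}

#' @rdname spectrobind-tidiers
#' @export
glance.binding_fit <- function(x, ...) {
  tibble::tibble(K_a = x$K_a, K_d = x$K_d, I0 = x$I0, Ic = x$Ic,
                 nobs = nrow(x$data))
}

#' @rdname spectrobind-tidiers
#' @export
tidy.partition_fit <- function(x, ...) {
  one_term(c("K_p", "delta_A_max"), c(x$K_p, x$delta_A_max),
           c(x$K_p_se, x$delta_A_max_se))
}

#' @rdname spectrobind-tidiers
#' @export
glance.partition_fit <- function(x, ...) {
  tibble::tibble(K_p = x$K_p, delta_A_max = x$delta_A_max, mode = x$mode,
                 gamma = x$gamma, upper_bound_flag = x$upper_bound_flag,
                 nobs = nrow(x$data))
}

#' @rdname spectrobind-tidiers
#' @export
tidy.transition_fit <- function(x, ...) {
  one_term(c("T_m", "r_low_T", "r_high_T", "width"),
           c(x$T_m, x$r_low_T, x$r_high_T, x$width),
           c(x$T_m_se, NA_real_, NA_real_, x$width_se))
}

#' @rdname spectrobind-tidiers
#' @export
glance.transition_fit <- function(x, ...) {
  tibble::tibble(T_m = x$T_m, r_low_T = x$r_low_T, r_high_T = x$r_high_T,
                 width = x$width, model = x$model, nobs = nrow(x$data))
}

#' @rdname spectrobind-tidiers
#' @export
tidy.decay_fit <- function(x, ...) {
  one_term(c("k", "A0", "A_inf"), c(x$k, x$A0, x$A_inf),
           c(x$k_se, NA_real_, NA_real_))
}

#' @rdname spectrobind-tidiers
#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(k = x$k, t_half = x$t_half, A0 = x$A0, A_inf = x$A_inf,
                 nobs = nrow(x$data))
}

#' @rdname spectrobind-tidiers
#' @export
tidy.thermo_params <- function(x, ...) {
  one_term(c("dG", "dH", "dS"), c(x$dG, x$dH, x$dS),
           rep(NA_real_, 3))
}

#' @rdname spectrobind-tidiers
#' @export
glance.thermo_params <- function(x, ...) {
  tibble::tibble(dG = x$dG, dH = x$dH, dS = x$dS, T = x$T)
}

plot_fit_data <- function(data, xvar, yvar, xlab, ylab) {
  ggplot2::ggplot(data, ggplot2::aes(.data[[xvar]], .data[[yvar]])) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "steelblue") +
    ggplot2::labs(x = xlab, y = ylab)
}

#' Autoplot methods for spectrobind fit objects
#'
#' Each fitted object plots its data points with the fitted curve overlaid.
#'
#' @param object A fit object.
#' @param ... Unused.
#' @return A ggplot.
#' @name spectrobind-autoplot
NULL

#' @rdname spectrobind-autoplot
#' @export
autoplot.sv_fit <- function(object, ...) {
  plot_fit_data(object$data, "conc_M", "ratio", "[Q] (M)", expression(I[0] / I)) +
    ggplot2::ggtitle(sprintf("Stern-Volmer: K_SV = %.4g M^-1", object$K_SV))
}

#' @rdname spectrobind-autoplot
#' @export
autoplot.binding_fit <- function(object, ...) {
  plot_fit_data(object$data, "conc_M", "delta_I", "[ligand] (M)",
                expression(Delta * I)) +
    ggplot2::ggtitle(sprintf("1:1 isotherm: K_a = %.4g M^-1", object$K_a))
}

#' @rdname spectrobind-autoplot
#' @export
autoplot.partition_fit <- function(object, ...) {
  plot_fit_data(object$data, "lipid_conc_M", "delta_A", "[lipid] (M)",
                expression(Delta * A)) +
    ggplot2::ggtitle(sprintf("Partition: K_p = %.4g (%s)", object$K_p, object$mode))
}

#' @rdname spectrobind-autoplot
#' @export
autoplot.transition_fit <- function(object, ...) {
  plot_fit_data(object$data, "temperature_C", "r",
                "Temperature (°C)", "Anisotropy <r>") +
    ggplot2::ggtitle(sprintf("Phase transition: T_m = %.2f °C", object$T_m))
}

#' @rdname spectrobind-autoplot
#' @export
autoplot.decay_fit <- function(object, ...) {
  plot_fit_data(object$data, "time_h", "signal", "Time (h)", "Signal (AU)") +
    ggplot2::ggtitle(sprintf("First-order decay: t1/2 = %.3g h", object$t_half))
}
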