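#' Define a plasma protein composition
#'
#' A set of plasma proteins, each with a single-site association constant for
#' the drug and a plasma concentration, used for competitive distribution
#' estimates.
#'
#' @param name Protein names (unique).
#' @param Ka_M Association constants (M^-1), >= 0.
#' @param conc_M Protein concentrations (M), >= 0.
#' @return A tibble of class `plasma_composition`.
#' @export
#' @examples
#' plasma_composition(c("HSA", "AGP"), c(4016, 8184), c(600e-6, 15e-6))
plasma_composition <- function(name, Ka_M, conc_M) {
  if (length(name) < 1L) stop_invalid("composition needs at least one protein")
  if (anyDuplicated(name)) stop_invalid("protein names must be unique")
  if (any(Ka_M < 0) || any(conc_M < 0)) {
    stop_invalid("association constants and concentrations must be >= 0")
  }
  out <- tibble::tibble(name = as.character(name), Ka_M = as.numeric(Ka_M),
                        conc_M = as.numeric(conc_M))
  class(out) <- c("plasma_composition", class(out))
  out
}

#' Read a plasma composition file
#'
#' Header `name,Ka_M,conc_M`.
#' @param path File path.
#' @return A `plasma_composition`.
#' @export
read_plasma_composition <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  sep <- if (grepl("\t", body[1])) "\t" else ","
  tab <- utils::read.table(text = paste(body, collapse = "\n"), sep = sep,
                           header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("name", "Ka_M", "conc_M") %in% names(tab))) {
    stop_invalid(sprintf("'%s': expected columns name,Ka_M,conc_M", path))
  }
  plasma_composition(tab$name, as.numeric(tab$Ka_M), as.numeric(tab$conc_M))
}

#' Competitive equilibrium drug distribution among plasma proteins
#'
#' In the default (no-depletion) mode, valid when every protein is in excess
#' over the bound drug, the fraction of drug bound to protein i is
#' \deqn{f_i = \frac{K_{a,i}[P_i]}{1 + \sum_j K_{a,j}[P_j]}}
#' and the free fraction is \eqn{1 / (1 + \sum_j K_{a,j}[P_j])}; fractions
#' sum to one. When `drug_conc_M` is supplied, a mass-balance mode instead
#' solves the coupled 1:1 equilibria for the free drug concentration by
#' bisection, accounting for drug depletion of the protein sites.
#'
#' @param comp A `plasma_composition` (or data frame with `name`, `Ka_M`,
#'   `conc_M`).
#' @param drug_conc_M Optional total drug concentration (M) enabling the
#'   depletion-aware mode.
#' @return A tibble with columns `name`, `fraction` (of total drug), ending
#'   with a `"free"` row; fractions sum to 1.
#' @export
#' @examples
#' bound_fractions(plasma_composition(c("HSA", "AGP"),
#'                                    c(4016, 8184), c(600e-6, 15e-6)))
bound_fractions <- function(comp, drug_conc_M = NULL) {
  comp <- as_plasma(comp)
  if (is.null(drug_conc_M)) {
    s <- sum(comp$Ka_M * comp$conc_M)
    frac <- comp$Ka_M * comp$conc_M / (1 + s)
    free <- 1 / (1 + s)
  } else {
    if (drug_conc_M <= 0) stop_invalid("drug_conc_M must be > 0")
    # mass balance: D + sum_i P_i Ka_i D / (1 + Ka_i D) = D_tot, solved for
    # free drug D in (0, D_tot] by bisection (the left side is increasing in D)
    total_bound <- function(D) {
      D + sum(comp$conc_M * comp$Ka_M * D / (1 + comp$Ka_M * D))
    }
    lo <- 0
    hi <- drug_conc_M
    for (it in 1:200) {
      mid <- (lo + hi) / 2
      if (total_bound(mid) > drug_conc_M) hi <- mid else lo <- mid
    }
    D <- (lo + hi) / 2
    bound_i <- comp$conc_M * comp$Ka_M * D / (1 + comp$Ka_M * D)
    frac <- bound_i / drug_conc_M
    free <- D / drug_conc_M
  }
  tibble::tibble(name = c(comp$name, "free"), fraction = c(frac, free))
}

#' Bound fraction as a function of protein concentration
#'
#' Single-protein saturation curve f([P]) = Ka [P] / (1 + Ka [P]), e.g. the
#' fraction of drug protected by albumin as its concentration is raised.
#'
#' @param Ka_M Association constant (M^-1), >= 0.
#' @param conc_grid_M Protein concentrations (M), >= 0.
#' @return A tibble with columns `conc_M`, `fraction` (monotone increasing).
#' @export
bound_fraction_vs_protein_conc <- function(Ka_M, conc_grid_M) {
  if (any(Ka_M < 0) || any(conc_grid_M < 0)) {
    stop_invalid("Ka and concentrations must be >= 0")
  }
  x <- Ka_M * conc_grid_M
  tibble::tibble(conc_M = conc_grid_M, fraction = x / (1 + x))
}

as_plasma <- function(x) {
  if (inherits(x, "plasma_composition")) return(x)
  if (!all(c("name", "Ka_M", "conc_M") %in% names(x))) {
    stop_invalid("expected columns name, Ka_M, conc_M")
  }
  plasma_composition(x$name, x$Ka_M, x$conc_M)
}
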