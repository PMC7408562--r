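# Condition helpers: every user-facing error carries a class so callers (and
# the CLI) can distinguish bad inputs from failed fits.
stop_invalid <- function(msg) {
  stop(structure(class = c("spectrobind_invalid_input", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
stop_range <- function(msg) {
  stop(structure(class = c("spectrobind_range_error", "spectrobind_invalid_input",
                           "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
stop_param <- function(msg) {
  stop(structure(class = c("spectrobind_invalid_parameter", "spectrobind_invalid_input",
                           "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
stop_fit <- function(msg, best_residual = NA_real_) {
  stop(structure(class = c("spectrobind_fit_failure", "error", "condition"),
                 list(message = msg, call = sys.call(-1),
                      best_residual = best_residual)))
}
stop_mismatch <- function(msg) {
  stop(structure(class = c("spectrobind_model_mismatch", "spectrobind_fit_failure",
                           "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Gas constant
#'
#' R = 8.3145 J mol^-1 K^-1, the value used throughout for thermodynamic
#' conversions.
#' @export
R_GAS <- 8.3145

celsius_to_kelvin <- function(t_c) t_c + 273.15

# ---- delimited-text tables with '#' comment headers --------------------------

# Reads a comma- or tab-delimited table; returns the data with parsed
# '# key: value' metadata in attr(, "meta"). Rejects non-numeric cells.
read_delim_table <- function(path, n_cols = NULL) {
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^\\s*#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    m <- regmatches(ml, regexec("^\\s*#\\s*([A-Za-z0-9_.]+)\\s*:\\s*(.*)$", ml))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- trimws(m[3])
  }
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(body) < 2L) stop_invalid(sprintf("'%s': no data rows found", path))
  sep <- if (grepl("\t", body[1])) "\t" else ","
  tab <- utils::read.table(text = paste(body, collapse = "\n"), sep = sep,
                           header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!is.null(n_cols) && ncol(tab) < n_cols) {
    stop_invalid(sprintf("'%s': expected at least %d columns, found %d",
                         path, n_cols, ncol(tab)))
  }
  for (j in seq_len(min(2L, ncol(tab)))) {
    # the leading (axis, value) columns must be numeric; trailing columns may
    # carry labels or flags
    if (!is.numeric(tab[[j]])) {
      suppressWarnings(num <- as.numeric(tab[[j]]))
      if (anyNA(num)) stop_invalid(sprintf("'%s': column '%s' is not numeric",
                                           path, names(tab)[j]))
      tab[[j]] <- num
    }
  }
  out <- tibble::as_tibble(tab)
  attr(out, "meta") <- meta
  out
}

write_delim_table <- function(df, path, col_names = names(df),
                              comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  writeLines(paste(col_names, collapse = ","), con)
  cols <- lapply(df, function(col) {
    if (is.numeric(col)) formatC(col, digits = 10, format = "g") else as.character(col)
  })
  writeLines(do.call(paste, c(cols, sep = ",")), con)
  invisible(path)
}

# nlsLM with bounded jittered restarts from a supplied initializer.
# start_fn(jitter_sd) must return a named list of start values.
fit_nls_restarts <- function(formula, data, start_fn, lower, upper,
                             max_restarts = 5L, seed_jitter = NULL) {
  best <- NULL
  best_rss <- Inf
  jitters <- c(0, rep(0.2, max_restarts))
  for (k in seq_along(jitters)) {
    start <- start_fn(jitters[k])
    start <- mapply(function(v, lo, hi) min(max(v, lo), hi),
                    start, lower[names(start)], upper[names(start)],
                    SIMPLIFY = FALSE)
    fit <- tryCatch(
      minpack.lm::nlsLM(formula, data = data, start = start,
                        lower = lower[names(start)], upper = upper[names(start)],
                        control = minpack.lm::nls.lm.control(
                          maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (rss < best_rss) {
        best <- fit
        best_rss <- rss
      }
      if (rss == 0) break
    }
  }
  if (is.null(best)) {
    stop_fit("nonlinear fit failed to converge after bounded restarts",
             best_residual = best_rss)
  }
  best
}
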