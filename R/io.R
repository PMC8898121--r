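#' CSV readers and writers
#'
#' All formats are plain comma-separated UTF-8 text with a mandatory header
#' row and '.' as the decimal separator:
#'
#' * extinction table: `wavelength_nm,eps_hbo2,eps_hb,eps_methb`
#' * spectrum: `wavelength_nm,optical_density`
#' * MetHb time series: `time_min,methb`
#' * force curve: `indentation_nm,force_nn`
#' * kinetic time series (written): `time_min,methb_um,fe_um,hbo2_um,rate_um_per_min`
#'
#' @name cli_io
NULL

# read a CSV and validate that the named columns exist and are numeric;
# errors name the offending column (and first offending row for type errors)
read_numeric_csv <- function(path, columns) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    stop(path, ": file has a header but no data rows", call. = FALSE)
  }
  missing <- setdiff(columns, names(df))
  if (length(missing)) {
    stop(path, ": missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in columns) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      stop(path, ": column '", col, "' is not numeric (first bad row: ",
           if (length(bad)) bad[1] else "NA", ")", call. = FALSE)
    }
    if (anyNA(v)) {
      stop(path, ": column '", col, "' contains missing values (first at row ",
           which(is.na(v))[1], ")", call. = FALSE)
    }
  }
  df[columns]
}

#' Read an extinction-coefficient table from CSV
#'
#' @param path CSV file with columns
#'   `wavelength_nm,eps_hbo2,eps_hb,eps_methb`.
#' @return an [extinction_table()].
#' @export
read_extinction_csv <- function(path) {
  df <- read_numeric_csv(path, c("wavelength_nm", "eps_hbo2", "eps_hb",
                                 "eps_methb"))
  extinction_table(df$wavelength_nm, df$eps_hbo2, df$eps_hb, df$eps_methb)
}

#' Read an absorbance spectrum from CSV
#'
#' @param path CSV file with columns `wavelength_nm,optical_density`.
#' @param path_length_cm optical path length, cm.
#' @return an [hb_spectrum()].
#' @export
read_spectrum_csv <- function(path, path_length_cm = 1) {
  df <- read_numeric_csv(path, c("wavelength_nm", "optical_density"))
  hb_spectrum(df$wavelength_nm, df$optical_density, path_length_cm)
}

#' Read a methemoglobin time series from CSV
#'
#' @param path CSV file with columns `time_min,methb`.
#' @param unit unit of the `methb` column, `"um"` or `"percent"`; recorded
#'   as an attribute for downstream fitting.
#' @return a `data.frame` with columns `time_min`, `methb` and attribute
#'   `methb_unit`.
#' @export
read_methb_csv <- function(path, unit = c("um", "percent")) {
  unit <- match.arg(unit)
  df <- read_numeric_csv(path, c("time_min", "methb"))
  if (any(diff(df$time_min) < 0)) {
    stop(path, ": time_min must be nondecreasing", call. = FALSE)
  }
  attr(df, "methb_unit") <- unit
  df
}

#' Read a force-indentation curve from CSV
#'
#' @param path CSV file with columns `indentation_nm,force_nn`.
#' @return a [force_curve()].
#' @export
read_force_csv <- function(path) {
  df <- read_numeric_csv(path, c("indentation_nm", "force_nn"))
  force_curve(df$indentation_nm, df$force_nn)
}

#' Write a kinetic time series to CSV
#'
#' @param ts a `"kinetic_timeseries"` data.frame from [ode_solve()] or
#'   [kinetic_timeseries()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_kinetics_csv <- function(ts, path) {
  stopifnot(inherits(ts, "kinetic_timeseries"))
  utils::write.csv(as.data.frame(ts), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a fit report
#'
#' Writes a parameter CSV (`<stem>.csv`) and a human-readable text summary
#' (`<stem>.txt`) for one or more kinetic curve fits. The summary records
#' the package version and, when provided, the seed of the run, so results
#' are traceable.
#'
#' @param fits a `"curve_fit_result"` or list of them (see
#'   [fit_methb_curve()]); fits must carry resolved parameter sets.
#' @param stem output path stem (without extension).
#' @param seed optional integer seed to record in the summary.
#' @return named character vector with the paths written, invisibly.
#' @export
write_fit_report <- function(fits, stem, seed = NULL) {
  if (inherits(fits, "curve_fit_result")) fits <- list(fits)
  if (!length(fits)) stop("write_fit_report(): no fits", call. = FALSE)
  if (any(vapply(fits, function(f) is.null(f$params), logical(1)))) {
    stop("write_fit_report(): all fits must carry resolved parameters ",
         "(refit with fix_a)", call. = FALSE)
  }
  rows <- do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    data.frame(curve = i, y0_um = f$params$y0, z0_um = f$params$z0,
               a_um = f$params$a, beta = f$params$beta,
               gamma = f$params$gamma, r2 = f$r2,
               n_points = f$n_points, converged = f$converged)
  }))
  csv_path <- paste0(stem, ".csv")
  txt_path <- paste0(stem, ".txt")
  utils::write.csv(rows, csv_path, row.names = FALSE, quote = FALSE)
  ver <- as.character(utils::packageVersion("ferrokin"))
  lines <- c(
    sprintf("ferrokin %s - methemoglobin kinetic fit report", ver),
    if (!is.null(seed)) sprintf("seed: %d", as.integer(seed)),
    sprintf("curves fitted: %d", nrow(rows)),
    "",
    vapply(seq_len(nrow(rows)), function(i) {
      sprintf("curve %d (y0 = %g uM): beta = %.4g, gamma = %.4g, R2 = %.4f%s",
              rows$curve[i], rows$y0_um[i], rows$beta[i], rows$gamma[i],
              rows$r2[i], if (rows$converged[i]) "" else " [not converged]")
    }, character(1))
  )
  writeLines(lines, txt_path)
  invisible(c(csv = csv_path, txt = txt_path))
}
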