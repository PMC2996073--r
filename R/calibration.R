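#' Beer's-law calibration curve
#'
#' Ordinary least-squares fit of absorbance on concentration for one
#' analyte at one analytical wavelength. The intercept is always fitted
#' (not forced through zero): real calibrations carry small nonzero
#' intercepts and forcing the origin would hide them. The reported
#' correlation is the Pearson r (not r^2), and the validity range is the
#' span of the calibration concentrations (the Beer's-law linearity limit).
#'
#' @param concentrations Concentrations in ug/ml, length >= 2, not all equal.
#' @param absorbances Absorbances in AU, same length.
#' @param analyte Analyte name.
#' @param wavelength Analytical wavelength in nm.
#' @return An object of class `calibration_curve` with fields `analyte`,
#'   `wavelength`, `slope` (AU per ug/ml), `intercept` (AU), `correlation`,
#'   `range_low`, `range_high` (ug/ml) and `n_points`.
#' @examples
#' fit_beers_law(c(2, 4, 6, 8, 10, 12),
#'               0.01713 + 0.08503 * c(2, 4, 6, 8, 10, 12),
#'               analyte = "ATL", wavelength = 224.20)
#' @export
fit_beers_law <- function(concentrations, absorbances, analyte = "",
                          wavelength = NA_real_) {
  concentrations <- as.numeric(concentrations)
  absorbances <- as.numeric(absorbances)
  if (length(concentrations) != length(absorbances))
    stop("concentrations and absorbances must have equal length", call. = FALSE)
  if (length(concentrations) < 2L)
    stop("need at least 2 calibration points", call. = FALSE)
  if (diff(range(concentrations)) == 0)
    stop("degenerate design: all concentrations identical", call. = FALSE)
  fit <- stats::lm(absorbances ~ concentrations)
  co <- stats::coef(fit)
  r <- if (diff(range(absorbances)) == 0) 0 else
    stats::cor(concentrations, absorbances)
  structure(
    list(analyte = as.character(analyte)[1], wavelength = wavelength,
         slope = unname(co[2]), intercept = unname(co[1]), correlation = r,
         range_low = min(concentrations), range_high = max(concentrations),
         n_points = length(concentrations)),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %s at %.2f nm\n", x$analyte, x$wavelength))
  cat(sprintf("  A = %.5f x c + %.5f   (c in ug/ml)\n", x$slope, x$intercept))
  cat(sprintf("  r = %.4f over %g-%g ug/ml (n = %d)\n",
              x$correlation, x$range_low, x$range_high, x$n_points))
  invisible(x)
}

#' Mean specific absorptivity from replicate dilutions
#'
#' The specific absorptivity A(1 g/100 ml, 1 cm) — the absorbance of a
#' 1 g/100 ml solution in a 1 cm cell — estimated as the mean over
#' independent dilutions of absorbance / concentration, with concentration
#' converted from ug/ml (1 g/100 ml = 1e4 ug/ml). These means are the
#' coefficients entering the simultaneous-equation matrix.
#'
#' @param concentrations Concentrations in ug/ml, all > 0.
#' @param absorbances Matching absorbances in AU.
#' @param wavelength Analytical wavelength in nm (metadata only).
#' @return The mean absorptivity in A(1 g/100 ml, 1 cm) units.
#' @examples
#' mean_absorptivity(10, 0.8503)  # single dilution -> 850.3
#' @export
mean_absorptivity <- function(concentrations, absorbances, wavelength = NA_real_) {
  concentrations <- as.numeric(concentrations)
  absorbances <- as.numeric(absorbances)
  if (length(concentrations) < 1L)
    stop("need at least one dilution", call. = FALSE)
  if (length(concentrations) != length(absorbances))
    stop("concentrations and absorbances must have equal length", call. = FALSE)
  if (any(concentrations <= 0))
    stop("invalid dilution: concentrations must be > 0", call. = FALSE)
  mean(absorbances / concentrations) * 1e4
}

#' Is a concentration inside a curve's Beer's-law linearity range?
#'
#' Closed-interval test against the curve's validity range. Quantification
#' outside the linearity range should trigger a downstream warning; this
#' predicate only reports the flag.
#'
#' @param curve A [fit_beers_law()] result (or any list with `range_low`,
#'   `range_high`).
#' @param concentration Concentration(s) in ug/ml.
#' @return Logical, `TRUE` iff `range_low <= concentration <= range_high`.
#' @export
check_beers_range <- function(curve, concentration) {
  stopifnot(is.numeric(curve$range_low), is.numeric(curve$range_high))
  concentration >= curve$range_low & concentration <= curve$range_high
}

#' Read a calibration series from CSV
#'
#' Format: optional `# analyte=` and `# wavelength_nm=` comment lines, a
#' `concentration_ug_per_ml,absorbance` header, then one row per level.
#'
#' @param path Path to the CSV file.
#' @return A data.frame with columns `concentration`, `absorbance` and
#'   attributes `analyte`, `wavelength`.
#' @export
read_calibration_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  analyte <- ""; wavelength <- NA_real_
  i <- 1L
  while (i <= length(lines) && grepl("^\\s*#", lines[i])) {
    kv <- sub("^\\s*#\\s*", "", lines[i])
    key <- trimws(sub("=.*$", "", kv))
    val <- trimws(sub("^[^=]*=", "", kv))
    if (key == "analyte") analyte <- val
    if (key == "wavelength_nm") wavelength <- as.numeric(val)
    i <- i + 1L
  }
  if (i > length(lines) ||
      !grepl("^\\s*concentration_ug_per_ml\\s*,\\s*absorbance\\s*$", lines[i]))
    stop("line ", i, ": expected header 'concentration_ug_per_ml,absorbance'",
         call. = FALSE)
  df <- utils::read.csv(text = lines[seq(i, length(lines))],
                        col.names = c("concentration", "absorbance"))
  attr(df, "analyte") <- analyte
  attr(df, "wavelength") <- wavelength
  df
}

#' Serialize a calibration curve to a key-value config block
#'
#' Writes (or returns) the curve's fields as `key = value` lines mirroring
#' the usual optical-characteristics table of a method report: analyte,
#' wavelength, Beer's-law limits, slope, intercept, correlation coefficient.
#'
#' @param curve A [fit_beers_law()] result.
#' @param path Optional output path; when `NULL` the lines are returned.
#' @return Character vector of lines, invisibly when written to `path`.
#' @export
write_calibration_curve <- function(curve, path = NULL) {
  stopifnot(inherits(curve, "calibration_curve"))
  lines <- c(
    sprintf("analyte = %s", curve$analyte),
    sprintf("wavelength_nm = %s", format(curve$wavelength, digits = 15)),
    sprintf("beers_range_ug_per_ml = %s-%s",
            format(curve$range_low, digits = 15),
            format(curve$range_high, digits = 15)),
    sprintf("slope = %s", format(curve$slope, digits = 15)),
    sprintf("intercept = %s", format(curve$intercept, digits = 15)),
    sprintf("correlation = %s", format(curve$correlation, digits = 15)),
    sprintf("n_points = %d", curve$n_points)
  )
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
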