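#' UV absorbance spectrum
#'
#' Container for a single-beam UV absorbance scan: a strictly increasing
#' wavelength grid (nm) with one absorbance reading (AU) per grid point.
#' The default instrument range is 200--400 nm, the scan range of a typical
#' double-beam UV spectrophotometer; it can be widened for other hardware.
#'
#' @param wavelengths Numeric vector of wavelengths in nm, strictly
#'   increasing, length >= 2.
#' @param absorbances Numeric vector of absorbances in AU, same length as
#'   `wavelengths`, all finite.
#' @param pathlength Cell pathlength in cm (default 1).
#' @param label Free-text sample or analyte identifier.
#' @param concentration Concentration in ug/ml, or `NULL` when unknown
#'   (e.g. an unknown sample scan).
#' @param instrument_range Length-2 numeric, the admissible wavelength
#'   window in nm. All grid points must fall inside it.
#'
#' @return An object of class `uv_spectrum`.
#' @examples
#' s <- uv_spectrum(c(250, 252), c(0.4, 0.6))
#' absorbance_at(s, 251)
#' @export
uv_spectrum <- function(wavelengths, absorbances, pathlength = 1,
                        label = "", concentration = NULL,
                        instrument_range = c(200, 400)) {
  wavelengths <- as.numeric(wavelengths)
  absorbances <- as.numeric(absorbances)
  if (length(wavelengths) < 2L)
    stop("a spectrum needs at least 2 grid points", call. = FALSE)
  if (length(absorbances) != length(wavelengths))
    stop("wavelengths and absorbances must have equal length", call. = FALSE)
  if (anyNA(wavelengths) || any(!is.finite(wavelengths)))
    stop("wavelengths must be finite", call. = FALSE)
  if (anyNA(absorbances) || any(!is.finite(absorbances)))
    stop("absorbances must be finite", call. = FALSE)
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing (no duplicates)", call. = FALSE)
  stopifnot(length(instrument_range) == 2L, instrument_range[1] < instrument_range[2])
  if (wavelengths[1] < instrument_range[1] ||
      wavelengths[length(wavelengths)] > instrument_range[2])
    stop(sprintf("wavelengths outside instrument range [%g, %g] nm",
                 instrument_range[1], instrument_range[2]), call. = FALSE)
  if (!is.numeric(pathlength) || length(pathlength) != 1L || pathlength <= 0)
    stop("pathlength must be a single positive number (cm)", call. = FALSE)
  if (!is.null(concentration)) {
    concentration <- as.numeric(concentration)
    stopifnot(length(concentration) == 1L, is.finite(concentration))
  }
  structure(
    list(wavelengths = wavelengths, absorbances = absorbances,
         pathlength = pathlength, label = as.character(label)[1],
         concentration = concentration, instrument_range = instrument_range),
    class = "uv_spectrum"
  )
}

#' @export
print.uv_spectrum <- function(x, ...) {
  cat(sprintf("<uv_spectrum> %s\n", if (nzchar(x$label)) x$label else "(unlabelled)"))
  cat(sprintf("  %d points, %.2f-%.2f nm, pathlength %g cm\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              x$pathlength))
  if (!is.null(x$concentration))
    cat(sprintf("  concentration %g ug/ml\n", x$concentration))
  invisible(x)
}

#' Read a spectrum from a two-column CSV file
#'
#' Expected format: optional leading comment lines starting with `#`
#' (`# label=`, `# concentration_ug_per_ml=`, `# pathlength_cm=`), a header
#' line `wavelength_nm,absorbance`, then one `wavelength,absorbance` row per
#' grid point ('.' decimal separator, UTF-8). Rows are sorted by wavelength
#' on read; duplicate wavelengths and non-numeric values are parse errors
#' that name the offending line.
#'
#' @param path Path to the CSV file.
#' @param instrument_range Admissible wavelength window, see [uv_spectrum()].
#' @return A [uv_spectrum()] object.
#' @seealso [write_spectrum()]
#' @export
read_spectrum <- function(path, instrument_range = c(200, 400)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  meta <- list(label = "", concentration = NULL, pathlength = 1)
  i <- 1L
  while (i <= length(lines) && grepl("^\\s*#", lines[i])) {
    kv <- sub("^\\s*#\\s*", "", lines[i])
    if (grepl("=", kv, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", kv))
      val <- trimws(sub("^[^=]*=", "", kv))
      if (key == "label") meta$label <- val
      if (key == "concentration_ug_per_ml") meta$concentration <- as.numeric(val)
      if (key == "pathlength_cm") meta$pathlength <- as.numeric(val)
    }
    i <- i + 1L
  }
  if (i > length(lines) || !grepl("^\\s*wavelength_nm\\s*,\\s*absorbance\\s*$", lines[i]))
    stop("line ", i, ": expected header 'wavelength_nm,absorbance'", call. = FALSE)
  first_data <- i + 1L
  data_lines <- lines[seq(first_data, length.out = max(0L, length(lines) - i))]
  keep <- nzchar(trimws(data_lines))
  wl <- ab <- numeric(sum(keep))
  j <- 0L
  for (k in seq_along(data_lines)) {
    if (!keep[k]) next
    fields <- strsplit(data_lines[k], ",", fixed = TRUE)[[1]]
    lineno <- first_data + k - 1L
    if (length(fields) != 2L)
      stop("line ", lineno, ": expected 2 comma-separated fields", call. = FALSE)
    vals <- suppressWarnings(as.numeric(trimws(fields)))
    if (anyNA(vals))
      stop("line ", lineno, ": non-numeric value", call. = FALSE)
    j <- j + 1L
    wl[j] <- vals[1]; ab[j] <- vals[2]
  }
  if (anyDuplicated(wl)) {
    dup <- wl[duplicated(wl)][1]
    stop("duplicate wavelength ", dup, " nm in ", path, call. = FALSE)
  }
  o <- order(wl)
  uv_spectrum(wl[o], ab[o], pathlength = meta$pathlength, label = meta$label,
              concentration = meta$concentration,
              instrument_range = instrument_range)
}

#' Write a spectrum to CSV
#'
#' Inverse of [read_spectrum()]: metadata comments, the
#' `wavelength_nm,absorbance` header, then one row per grid point with 15
#' significant digits so that a read/write round trip is lossless.
#'
#' @param s A [uv_spectrum()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "uv_spectrum"))
  hdr <- c(sprintf("# label=%s", s$label),
           if (!is.null(s$concentration))
             sprintf("# concentration_ug_per_ml=%s",
                     format(s$concentration, digits = 15)),
           sprintf("# pathlength_cm=%s", format(s$pathlength, digits = 15)),
           "wavelength_nm,absorbance")
  rows <- paste(format(s$wavelengths, digits = 15, trim = TRUE, scientific = FALSE),
                format(s$absorbances, digits = 15, trim = TRUE),
                sep = ",")
  con <- try(file(path, "w", encoding = "UTF-8"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot write to ", path, call. = FALSE)
  on.exit(close(con))
  writeLines(c(hdr, rows), con)
  invisible(path)
}

#' Absorbance at an arbitrary wavelength
#'
#' Linear interpolation between the two bracketing grid points; a query that
#' hits a grid point exactly returns the stored value. Linear (rather than
#' spline) interpolation is deliberate: the method only ever reads
#' absorbances at fixed analytical wavelengths, and linear interpolation is
#' transparent and monotone between grid points.
#'
#' @param s A [uv_spectrum()].
#' @param wavelength Query wavelength(s) in nm; must lie within the grid.
#' @return Absorbance(s) in AU.
#' @export
absorbance_at <- function(s, wavelength) {
  stopifnot(inherits(s, "uv_spectrum"))
  wavelength <- as.numeric(wavelength)
  rng <- range(s$wavelengths)
  if (any(wavelength < rng[1] | wavelength > rng[2]))
    stop(sprintf("wavelength outside spectrum grid [%g, %g] nm", rng[1], rng[2]),
         call. = FALSE)
  stats::approx(s$wavelengths, s$absorbances, xout = wavelength,
                method = "linear", ties = "ordered")$y
}

#' Locate the absorption maximum
#'
#' Finds the wavelength of the largest absorbance inside `window` and
#' refines it by fitting a parabola through the discrete maximum and its two
#' neighbours (the standard three-point vertex formula). Ties on the
#' discrete grid are broken toward the lower wavelength; a maximum sitting
#' on the window edge is returned unrefined. A flat spectrum has no
#' distinct maximum and is an error.
#'
#' @param s A [uv_spectrum()].
#' @param window Optional `c(low, high)` nm restricting the search; default
#'   is the whole grid. Must overlap the grid in >= 3 points.
#' @return The estimated lambda-max in nm.
#' @export
find_lambda_max <- function(s, window = NULL) {
  stopifnot(inherits(s, "uv_spectrum"))
  wl <- s$wavelengths; ab <- s$absorbances
  if (!is.null(window)) {
    stopifnot(length(window) == 2L, window[1] < window[2])
    if (window[2] < min(wl) || window[1] > max(wl))
      stop("window outside spectrum grid", call. = FALSE)
    sel <- wl >= window[1] & wl <= window[2]
    wl <- wl[sel]; ab <- ab[sel]
  }
  if (length(wl) < 3L)
    stop("need at least 3 grid points in window", call. = FALSE)
  if (diff(range(ab)) == 0)
    stop("no distinct maximum: spectrum is flat in window", call. = FALSE)
  i <- which.max(ab)  # which.max takes the first, i.e. lowest wavelength
  if (i == 1L || i == length(wl)) return(wl[i])
  # parabolic vertex through (i-1, i, i+1); assumes locally even spacing.
  # An exact plateau (next point equal) keeps the lower wavelength: the
  # tie-break rule dominates refinement on degenerate inputs.
  y1 <- ab[i - 1L]; y2 <- ab[i]; y3 <- ab[i + 1L]
  if (y3 == y2) return(wl[i])
  denom <- y1 - 2 * y2 + y3
  if (denom == 0) return(wl[i])
  h <- (wl[i + 1L] - wl[i - 1L]) / 2
  delta <- 0.5 * (y1 - y3) / denom
  wl[i] + delta * h
}
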