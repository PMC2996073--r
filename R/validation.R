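#' Percent relative standard deviation
#'
#' The precision metric used throughout analytical method validation:
#' `100 * sd(x) / mean(x)` with the sample (n-1 denominator) standard
#' deviation, conventional for the small replicate counts (n = 3-5) of
#' validation work.
#'
#' @param values Numeric vector of replicate measurements, length >= 2,
#'   nonzero mean.
#' @return The %RSD.
#' @examples
#' percent_rsd(c(1, 2, 3))  # 50
#' @export
percent_rsd <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("insufficient replicates: need n >= 2 for an RSD", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("undefined RSD: mean is zero", call. = FALSE)
  100 * stats::sd(values) / m
}

#' Tablet assay against label claim
#'
#' Back-calculates mg of drug per tablet from solved working-solution
#' concentrations through the dilution chain:
#' `amount_found = c[ug/ml] * dilution_factor * stock_volume[ml] *
#' average_tablet_weight / (sample_weight * 1000)`,
#' then summarizes the replicates as mean, SD, %RSD and % of label claim.
#'
#' @param solved_concentrations Solved concentration per replicate, ug/ml.
#' @param dilution_factor Dilution from stock to measured solution, >= 1.
#' @param stock_volume Stock flask volume in ml.
#' @param sample_weight Powder weight taken, mg.
#' @param average_tablet_weight Average tablet weight, mg.
#' @param label_claim Declared content, mg/tablet.
#' @param analyte Analyte name.
#' @return An object of class `assay_report`: `analyte`, `label_claim`,
#'   `amount_found` (mean mg/tablet), `sd`, `rsd_percent`,
#'   `percent_label_claim`, `n`, and the per-replicate `amounts`.
#' @examples
#' assay_tablets(c(25, 25), dilution_factor = 20, stock_volume = 100,
#'               sample_weight = 200, average_tablet_weight = 200,
#'               label_claim = 50)
#' @export
assay_tablets <- function(solved_concentrations, dilution_factor,
                          stock_volume, sample_weight, average_tablet_weight,
                          label_claim, analyte = "") {
  solved_concentrations <- as.numeric(solved_concentrations)
  if (length(solved_concentrations) < 1L)
    stop("need at least one replicate", call. = FALSE)
  if (any(c(stock_volume, sample_weight, average_tablet_weight,
            label_claim) <= 0) || dilution_factor < 1)
    stop("masses, volumes and label claim must be positive; dilution_factor >= 1",
         call. = FALSE)
  amounts <- solved_concentrations * dilution_factor * stock_volume *
    average_tablet_weight / (sample_weight * 1000)
  n <- length(amounts)
  s <- if (n >= 2L) stats::sd(amounts) else NA_real_
  structure(
    list(analyte = as.character(analyte)[1], label_claim = label_claim,
         amount_found = mean(amounts), sd = s,
         rsd_percent = if (n >= 2L) percent_rsd(amounts) else NA_real_,
         percent_label_claim = 100 * mean(amounts) / label_claim,
         n = n, amounts = amounts),
    class = "assay_report")
}

#' @export
print.assay_report <- function(x, ...) {
  cat(sprintf("<assay_report> %s (n = %d)\n", x$analyte, x$n))
  cat(sprintf("  label claim %.4g mg/tab, found %.4g mg/tab (%.2f%% of claim)\n",
              x$label_claim, x$amount_found, x$percent_label_claim))
  if (!is.na(x$sd))
    cat(sprintf("  SD %.4g mg/tab, %%RSD %.3g\n", x$sd, x$rsd_percent))
  invisible(x)
}

#' Spiked-recovery (standard-addition) statistics
#'
#' Per-replicate recovery of a known added amount:
#' `100 * (spiked_found - unspiked_found) / added`. Negative recoveries
#' are reported as computed, never clamped. A single unspiked baseline
#' (e.g. the mean of a preanalysis) is recycled across spiked replicates.
#'
#' @param unspiked_found Found amount(s) before spiking; length 1 or equal
#'   to `spiked_found`.
#' @param spiked_found Found amount per spiked replicate (same units).
#' @param added Known added amount, > 0 (same units).
#' @param level_percent Spike level as % of the analyte content.
#' @param analyte Analyte name.
#' @return An object of class `recovery_report`: `analyte`,
#'   `level_percent`, `n`, `mean_recovery_percent`, `rsd_percent`, and the
#'   per-replicate `recoveries`.
#' @examples
#' recovery_study(20, c(35.9, 36.1, 36.0), added = 16, level_percent = 80)
#' @export
recovery_study <- function(unspiked_found, spiked_found, added,
                           level_percent = NA_real_, analyte = "") {
  unspiked_found <- as.numeric(unspiked_found)
  spiked_found <- as.numeric(spiked_found)
  if (!is.numeric(added) || length(added) != 1L || added <= 0)
    stop("added amount must be a single positive value", call. = FALSE)
  if (length(unspiked_found) == 1L)
    unspiked_found <- rep(unspiked_found, length(spiked_found))
  if (length(unspiked_found) != length(spiked_found))
    stop("unspiked_found must be length 1 or match spiked_found", call. = FALSE)
  recoveries <- 100 * (spiked_found - unspiked_found) / added
  n <- length(recoveries)
  structure(
    list(analyte = as.character(analyte)[1], level_percent = level_percent,
         n = n, mean_recovery_percent = mean(recoveries),
         rsd_percent = if (n >= 2L) percent_rsd(recoveries) else NA_real_,
         recoveries = recoveries),
    class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %s at %g%% level (n = %d)\n",
              x$analyte, x$level_percent, x$n))
  cat(sprintf("  mean recovery %.2f%%, %%RSD %.3g\n",
              x$mean_recovery_percent, x$rsd_percent))
  invisible(x)
}

#' Repeatability, intra/inter-day precision and ruggedness
#'
#' Summarizes a precision study design:
#' * repeatability: %RSD of one session's replicates (typically n = 5);
#' * intra-day: %RSD within each day's replicate group; reported as the
#'   (min, max) range over all days and concentration levels;
#' * inter-day: %RSD across day means, per concentration level; reported
#'   as the (min, max) range over levels (the standard intermediate-
#'   precision convention, using day means rather than pooled raw
#'   replicates);
#' * ruggedness: per-analyst %RSD of each analyst's replicates.
#'
#' @param day_runs Replicates grouped by day: a list of concentration
#'   levels, each a list of per-day numeric vectors (>= 2 replicates
#'   each). A plain list of numeric vectors is treated as a single level.
#' @param analyst_runs Named list of per-analyst replicate vectors (>= 2
#'   each); may be empty.
#' @param repeatability_run Optional single-session replicate vector; when
#'   `NULL` the first day's replicates of the first level are used.
#' @return An object of class `precision_report`: `repeatability_rsd`,
#'   `intraday_rsd_range` (c(min, max)), `interday_rsd_range`,
#'   `analyst_rsds` (named), plus the per-day RSDs in `intraday_rsds`.
#' @examples
#' precision_study(
#'   day_runs = list(list(c(19.9, 20.1, 20.0), c(20.2, 20.1, 20.3))),
#'   analyst_runs = list(A1 = c(19.8, 20.2, 20.1), A2 = c(20.0, 20.1, 19.9)))
#' @export
precision_study <- function(day_runs, analyst_runs = list(),
                            repeatability_run = NULL) {
  if (!is.list(day_runs) || length(day_runs) == 0L)
    stop("day_runs must be a non-empty list", call. = FALSE)
  if (all(vapply(day_runs, is.numeric, logical(1))))
    day_runs <- list(day_runs)
  check_group <- function(g) {
    if (!is.numeric(g) || length(g) < 2L)
      stop("insufficient replicates: every group needs n >= 2", call. = FALSE)
    g
  }
  intraday <- unlist(lapply(day_runs, function(level)
    vapply(level, function(g) percent_rsd(check_group(g)), numeric(1))))
  interday <- vapply(day_runs, function(level) {
    if (length(level) < 2L)
      stop("inter-day precision needs >= 2 days per level", call. = FALSE)
    percent_rsd(vapply(level, function(g) mean(check_group(g)), numeric(1)))
  }, numeric(1))
  analyst_rsds <- vapply(analyst_runs, function(g)
    percent_rsd(check_group(g)), numeric(1))
  if (is.null(repeatability_run)) repeatability_run <- day_runs[[1]][[1]]
  structure(
    list(repeatability_rsd = percent_rsd(check_group(repeatability_run)),
         intraday_rsd_range = range(intraday),
         interday_rsd_range = range(interday),
         analyst_rsds = analyst_rsds,
         intraday_rsds = intraday),
    class = "precision_report")
}

#' @export
print.precision_report <- function(x, ...) {
  cat("<precision_report>\n")
  cat(sprintf("  repeatability %%RSD: %.3g\n", x$repeatability_rsd))
  cat(sprintf("  intra-day %%RSD range: %.3g - %.3g\n",
              x$intraday_rsd_range[1], x$intraday_rsd_range[2]))
  cat(sprintf("  inter-day %%RSD range: %.3g - %.3g\n",
              x$interday_rsd_range[1], x$interday_rsd_range[2]))
  if (length(x$analyst_rsds))
    cat("  ruggedness %RSD:",
        paste(sprintf("%s = %.3g", names(x$analyst_rsds), x$analyst_rsds),
              collapse = ", "), "\n")
  invisible(x)
}
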