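#' Gaussian band model of a pure-component UV spectrum
#'
#' A pure component's absorptivity curve is emulated as a sum of Gaussian
#' bands: `a(lambda) = sum_j h_j exp(-(lambda - c_j)^2 / (2 w_j^2))`, with
#' `a` in A(1 g/100 ml, 1 cm) units. Only three-wavelength absorptivity
#' anchors are published for the drugs modelled here, so the full curve
#' shape is an emulation with the right anchors, not a reconstruction of
#' the true spectra.
#'
#' @param analyte Analyte name.
#' @param centers Band centers in nm, within 190--410 nm.
#' @param widths Band standard deviations in nm, all > 0.
#' @param heights Peak absorptivities in A(1 g/100 ml, 1 cm), all >= 0.
#' @return An object of class `band_model`.
#' @seealso [preset_band_models()], [eval_band_model()]
#' @export
band_model <- function(analyte, centers, widths, heights) {
  centers <- as.numeric(centers); widths <- as.numeric(widths)
  heights <- as.numeric(heights)
  stopifnot(length(centers) >= 1L,
            length(widths) == length(centers),
            length(heights) == length(centers))
  if (any(widths <= 0)) stop("band widths must be > 0", call. = FALSE)
  if (any(centers < 190 | centers > 410))
    stop("band centers must lie within 190-410 nm", call. = FALSE)
  if (any(heights < 0)) stop("peak absorptivities must be >= 0", call. = FALSE)
  structure(list(analyte = as.character(analyte)[1], centers = centers,
                 widths = widths, heights = heights),
            class = "band_model")
}

#' Evaluate a band model's absorptivity
#'
#' @param model A [band_model()].
#' @param wavelengths Wavelength(s) in nm.
#' @return Absorptivity in A(1 g/100 ml, 1 cm) at each wavelength.
#' @export
eval_band_model <- function(model, wavelengths) {
  stopifnot(inherits(model, "band_model"))
  g <- exp(-outer(wavelengths, model$centers, "-")^2 /
             rep(2 * model$widths^2, each = length(wavelengths)))
  as.numeric(g %*% model$heights)
}

# Fix centers/widths and solve the band heights so the summed profile hits
# the absorptivity anchors exactly (linear system in the heights).
.anchored_band_model <- function(analyte, centers, widths,
                                 anchor_wavelengths, anchor_values) {
  g <- exp(-outer(anchor_wavelengths, centers, "-")^2 /
             rep(2 * widths^2, each = length(anchor_wavelengths)))
  heights <- as.numeric(solve(g, anchor_values))
  band_model(analyte, centers, widths, heights)
}

#' Preset band models for the three drugs
#'
#' Gaussian-band emulations of losartan potassium (LOK), atenolol (ATL)
#' and hydrochlorothiazide (HCTZ) whose absorptivities at the analytical
#' wavelengths reproduce the published coefficients (to machine precision,
#' the heights being solved against the anchors):
#'
#' * LOK: 320.25 at 251.60 nm (its analytical maximum) and 661.75 at
#'   224.20 nm;
#' * ATL (default, `atl_variant = "atl-hctz"`): 866.75 at 224.20 nm (its
#'   maximum), 8.1 at 251.60 nm and 106.0 at 271.60 nm;
#' * HCTZ: 1288 at 224.20 nm and 720 at 271.60 nm (its analytical
#'   maximum).
#'
#' ATL's published absorptivity at 224.20 nm differs between the two
#' published systems (380.50 when paired with LOK, 866.75 when paired with
#' HCTZ). `atl_variant = "lok-atl"` returns the ATL model consistent with
#' 380.50, so that simulations of each system round-trip exactly against
#' that system's matrix; the conflict is surfaced here rather than
#' averaged away.
#'
#' @param atl_variant Which published ATL absorptivity set the ATL model
#'   reproduces: `"atl-hctz"` (default) or `"lok-atl"`.
#' @return A named list of three [band_model()]s: `LOK`, `ATL`, `HCTZ`.
#' @export
preset_band_models <- function(atl_variant = c("atl-hctz", "lok-atl")) {
  atl_variant <- match.arg(atl_variant)
  lok <- .anchored_band_model("LOK",
    centers = c(205, 251.6), widths = c(10, 9),
    anchor_wavelengths = c(224.20, 251.60), anchor_values = c(661.75, 320.25))
  atl <- if (atl_variant == "atl-hctz") {
    .anchored_band_model("ATL",
      centers = c(224.2, 248, 277), widths = c(8, 6, 9),
      anchor_wavelengths = c(224.20, 251.60, 271.60),
      anchor_values = c(866.75, 8.1, 106.0))
  } else {
    .anchored_band_model("ATL",
      centers = c(224.2, 252), widths = c(8, 10),
      anchor_wavelengths = c(224.20, 251.60), anchor_values = c(380.50, 8.1))
  }
  hctz <- .anchored_band_model("HCTZ",
    centers = c(222, 271.6), widths = c(10, 11),
    anchor_wavelengths = c(224.20, 271.60), anchor_values = c(1288, 720))
  list(LOK = lok, ATL = atl, HCTZ = hctz)
}

# The component models matching a published two-component system.
.scenario_models <- function(preset = c("lok-atl", "atl-hctz")) {
  preset <- match.arg(preset)
  if (preset == "lok-atl") {
    mods <- preset_band_models(atl_variant = "lok-atl")
    mods[c("LOK", "ATL")]
  } else {
    mods <- preset_band_models(atl_variant = "atl-hctz")
    mods[c("ATL", "HCTZ")]
  }
}

#' Instrument noise model
#'
#' Additive iid Gaussian noise on each absorbance reading. The default sd
#' of 0.002 AU is chosen to give recovery/assay dispersion of the order
#' seen in routine double-beam UV work (%RSD a fraction of a percent to a
#' couple of percent at these working concentrations).
#'
#' @param absorbance_sd Noise standard deviation in AU, >= 0.
#' @param seed Optional integer seed; when set, every generator call using
#'   this model is reproducible (the RNG state is restored afterwards).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(absorbance_sd = 0.002, seed = NULL) {
  stopifnot(is.numeric(absorbance_sd), length(absorbance_sd) == 1L,
            absorbance_sd >= 0)
  if (!is.null(seed)) stopifnot(is.numeric(seed), length(seed) == 1L)
  structure(list(absorbance_sd = absorbance_sd, seed = seed),
            class = "noise_model")
}

# Run expr under a local seed (RNG state saved/restored); NULL seed = use
# the ambient RNG stream.
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv()),
      add = TRUE)
    set.seed(seed)
  }
  expr
}

#' Simulate a pure-component spectrum
#'
#' Forward Beer-Lambert synthesis on a regular grid:
#' `A(lambda) = c[g/100 ml] * a_model(lambda) * pathlength + noise`.
#'
#' @param model A [band_model()].
#' @param concentration Concentration in ug/ml, >= 0.
#' @param noise A [noise_model()]; use `noise_model(0)` for a noiseless
#'   spectrum.
#' @param grid Grid spacing in nm (default 0.2).
#' @param range Scan range in nm (default 200--400).
#' @param pathlength Cell pathlength in cm.
#' @return A [uv_spectrum()] carrying the analyte label and concentration.
#' @export
simulate_pure_spectrum <- function(model, concentration,
                                   noise = noise_model(), grid = 0.2,
                                   range = c(200, 400), pathlength = 1) {
  stopifnot(inherits(model, "band_model"), inherits(noise, "noise_model"))
  if (!is.numeric(concentration) || concentration < 0)
    stop("concentration must be >= 0", call. = FALSE)
  stopifnot(grid > 0)
  .with_seed(noise$seed, {
    wl <- seq(range[1], range[2], by = grid)
    a <- convert_units(concentration, "ug_per_ml", "g_per_100ml") *
      eval_band_model(model, wl) * pathlength
    if (noise$absorbance_sd > 0)
      a <- a + stats::rnorm(length(a), 0, noise$absorbance_sd)
    uv_spectrum(wl, a, pathlength = pathlength, label = model$analyte,
                concentration = concentration, instrument_range = range)
  })
}

#' Simulate a mixture spectrum
#'
#' Beer-Lambert additivity: the noiseless mixture is the pointwise sum of
#' the noiseless component spectra; instrument noise is added once, to the
#' sum.
#'
#' @param models List of [band_model()]s.
#' @param concentrations Concentrations in ug/ml, one per model, >= 0.
#' @inheritParams simulate_pure_spectrum
#' @return A [uv_spectrum()].
#' @export
simulate_mixture_spectrum <- function(models, concentrations,
                                      noise = noise_model(), grid = 0.2,
                                      range = c(200, 400), pathlength = 1) {
  stopifnot(inherits(noise, "noise_model"), grid > 0)
  if (length(models) != length(concentrations))
    stop("one concentration per component model required", call. = FALSE)
  if (any(concentrations < 0))
    stop("concentrations must be >= 0", call. = FALSE)
  .with_seed(noise$seed, {
    wl <- seq(range[1], range[2], by = grid)
    a <- numeric(length(wl))
    for (i in seq_along(models))
      a <- a + convert_units(concentrations[i], "ug_per_ml", "g_per_100ml") *
        eval_band_model(models[[i]], wl) * pathlength
    if (noise$absorbance_sd > 0)
      a <- a + stats::rnorm(length(a), 0, noise$absorbance_sd)
    lab <- paste(vapply(models, `[[`, "", "analyte"), collapse = "+")
    uv_spectrum(wl, a, pathlength = pathlength, label = lab,
                instrument_range = range)
  })
}

# Direct noisy absorbance readings of a mixture at analytical wavelengths
# (no full-scan synthesis; the bands are evaluated at the query points).
.measure_mixture <- function(models, concentrations, wavelengths, sd,
                             pathlength = 1) {
  a <- numeric(length(wavelengths))
  for (i in seq_along(models))
    a <- a + convert_units(concentrations[i], "ug_per_ml", "g_per_100ml") *
      eval_band_model(models[[i]], wavelengths) * pathlength
  if (sd > 0) a <- a + stats::rnorm(length(a), 0, sd)
  a
}

#' Measure a mixture at analytical wavelengths
#'
#' Convenience wrapper producing a [mixture_measurement()] directly from
#' band models and true concentrations — the forward model of the
#' quantification, used to exercise the solver end to end.
#'
#' @param models List of [band_model()]s.
#' @param concentrations True concentrations in ug/ml.
#' @param wavelengths Analytical wavelengths in nm.
#' @param noise A [noise_model()].
#' @param pathlength Cell pathlength in cm.
#' @return A [mixture_measurement()].
#' @export
measure_mixture <- function(models, concentrations, wavelengths,
                            noise = noise_model(), pathlength = 1) {
  stopifnot(inherits(noise, "noise_model"))
  if (length(models) != length(concentrations))
    stop("one concentration per component model required", call. = FALSE)
  .with_seed(noise$seed,
    mixture_measurement(wavelengths,
                        .measure_mixture(models, concentrations, wavelengths,
                                         noise$absorbance_sd, pathlength),
                        pathlength = pathlength))
}

#' Generate a Beer's-law calibration series
#'
#' One simulated pure-component scan per concentration level, read at the
#' analytical wavelength — the in-silico analogue of running a dilution
#' series on the instrument.
#'
#' @param model A [band_model()].
#' @param wavelength Analytical wavelength in nm.
#' @param concentrations Concentration levels in ug/ml.
#' @param noise A [noise_model()].
#' @param grid Grid spacing in nm for the underlying scans.
#' @param beers_range Optional `c(low, high)` ug/ml; levels outside it
#'   trigger a warning (the series would leave the linearity range).
#' @return A data.frame with columns `concentration` and `absorbance`.
#' @export
generate_calibration_series <- function(model, wavelength, concentrations,
                                        noise = noise_model(), grid = 0.2,
                                        beers_range = NULL) {
  stopifnot(inherits(model, "band_model"), inherits(noise, "noise_model"))
  if (!is.null(beers_range) &&
      any(concentrations < beers_range[1] | concentrations > beers_range[2]))
    warning("some levels fall outside the declared Beer's-law range",
            call. = FALSE)
  .with_seed(noise$seed, {
    ab <- vapply(concentrations, function(cc) {
      s <- simulate_pure_spectrum(model, cc,
                                  noise = noise_model(noise$absorbance_sd),
                                  grid = grid)
      absorbance_at(s, wavelength)
    }, numeric(1))
    data.frame(concentration = as.numeric(concentrations), absorbance = ab)
  })
}

#' Generate a spiked-recovery experiment
#'
#' Standard-addition style accuracy study: at each spike level, `n`
#' unspiked (base) and `n` spiked (base + added) mixture measurements at
#' the system's analytical wavelengths. The default design mirrors a
#' typical 80/100/120% three-level, triplicate study.
#'
#' @param preset Which published system to simulate, `"lok-atl"` (base
#'   20/20 ug/ml) or `"atl-hctz"` (base 8/2 ug/ml).
#' @param base_concentrations Unspiked (preanalyzed sample) concentrations
#'   in ug/ml, one per component; `NULL` = the preset's default.
#' @param spike_levels Spike levels as % of the base amount.
#' @param n Replicates per level.
#' @param noise A [noise_model()].
#' @return An object of class `recovery_experiment`: one element per level
#'   with `level_percent`, `added` (ug/ml per component), and `n x 2`
#'   absorbance matrices `unspiked` and `spiked`; the preset name and
#'   wavelengths are attached as attributes.
#' @seealso [analyze_recovery_experiment()]
#' @export
generate_recovery_experiment <- function(preset = c("lok-atl", "atl-hctz"),
                                         base_concentrations = NULL,
                                         spike_levels = c(80, 100, 120),
                                         n = 3, noise = noise_model()) {
  preset <- match.arg(preset)
  stopifnot(inherits(noise, "noise_model"), n >= 1, all(spike_levels > 0))
  models <- .scenario_models(preset)
  m <- vierordt_preset(preset)
  if (is.null(base_concentrations))
    base_concentrations <- if (preset == "lok-atl") c(20, 20) else c(8, 2)
  stopifnot(length(base_concentrations) == length(models))
  .with_seed(noise$seed, {
    levels <- lapply(spike_levels, function(lv) {
      added <- base_concentrations * lv / 100
      unspiked <- t(vapply(seq_len(n), function(i)
        .measure_mixture(models, base_concentrations, m$wavelengths,
                         noise$absorbance_sd), numeric(2)))
      spiked <- t(vapply(seq_len(n), function(i)
        .measure_mixture(models, base_concentrations + added, m$wavelengths,
                         noise$absorbance_sd), numeric(2)))
      colnames(unspiked) <- colnames(spiked) <- format(m$wavelengths, trim = TRUE)
      list(level_percent = lv, added = stats::setNames(added, m$components),
           unspiked = unspiked, spiked = spiked)
    })
    structure(levels, class = "recovery_experiment", preset = preset,
              wavelengths = m$wavelengths, components = m$components,
              base_concentrations = stats::setNames(base_concentrations,
                                                    m$components))
  })
}

#' Solve and summarize a recovery experiment
#'
#' Runs every measurement of a [generate_recovery_experiment()] through the
#' two-component solver and computes, per analyte and spike level, the
#' standard-addition recovery statistics via [recovery_study()].
#'
#' @param experiment A `recovery_experiment`.
#' @param m The matching [vierordt_preset()] matrix; defaults to the one
#'   the experiment was generated for.
#' @return A data.frame with one row per analyte x level: `analyte`,
#'   `level_percent`, `added_ug_per_ml`, `n`, `mean_recovery_percent`,
#'   `rsd_percent`.
#' @export
analyze_recovery_experiment <- function(experiment,
                                        m = vierordt_preset(attr(experiment, "preset"))) {
  stopifnot(inherits(experiment, "recovery_experiment"))
  comps <- attr(experiment, "components")
  rows <- list()
  for (lev in experiment) {
    un <- apply(lev$unspiked, 1, function(a)
      solve_two_component(m, a)$concentrations_ug_per_ml)
    sp <- apply(lev$spiked, 1, function(a)
      solve_two_component(m, a)$concentrations_ug_per_ml)
    for (k in seq_along(comps)) {
      rep_k <- recovery_study(unspiked_found = un[k, ], spiked_found = sp[k, ],
                              added = lev$added[[k]],
                              level_percent = lev$level_percent,
                              analyte = comps[k])
      rows[[length(rows) + 1L]] <- data.frame(
        analyte = comps[k], level_percent = lev$level_percent,
        added_ug_per_ml = lev$added[[k]], n = rep_k$n,
        mean_recovery_percent = rep_k$mean_recovery_percent,
        rsd_percent = rep_k$rsd_percent)
    }
  }
  do.call(rbind, rows)
}

#' Generate replicate tablet-assay samples
#'
#' Emulates the tablet assay: powder equivalent to one tablet's content is
#' taken into a volumetric flask, diluted to the working range, and each
#' replicate's absorbances are read at the system's analytical
#' wavelengths. Noiseless back-calculation through [assay_tablets()]
#' returns the label claims exactly; the true concentrations are included
#' for parameter-recovery testing.
#'
#' Defaults mirror a fixed-dose combination of 50/50 mg (LOK/ATL, working
#' solution 20/20 ug/ml after 25x dilution of a 100 ml stock) or
#' 50/12.5 mg (ATL/HCTZ, working solution 8/2 ug/ml after 62.5x dilution).
#'
#' @inheritParams generate_recovery_experiment
#' @param label_claims mg per tablet, one per component; `NULL` = preset
#'   default (`c(50, 50)` or `c(50, 12.5)`).
#' @param average_tablet_weight Average tablet weight in mg.
#' @param sample_weight Powder weight taken, in mg; `NULL` = one average
#'   tablet's worth.
#' @param stock_volume Stock flask volume in ml.
#' @param dilution_factor Dilution from stock to measured solution; `NULL`
#'   = preset default (25 or 62.5).
#' @param n Number of replicate determinations.
#' @return An object of class `assay_samples`: `measurements` (`n x 2`
#'   absorbance matrix), `true_concentrations_ug_per_ml` (at the measured
#'   dilution), and the design fields needed by [assay_tablets()].
#' @seealso [analyze_assay_samples()]
#' @export
generate_assay_samples <- function(preset = c("lok-atl", "atl-hctz"),
                                   label_claims = NULL,
                                   average_tablet_weight = 200,
                                   sample_weight = NULL,
                                   stock_volume = 100,
                                   dilution_factor = NULL,
                                   n = 5, noise = noise_model()) {
  preset <- match.arg(preset)
  stopifnot(inherits(noise, "noise_model"), n >= 1)
  models <- .scenario_models(preset)
  m <- vierordt_preset(preset)
  if (is.null(label_claims))
    label_claims <- if (preset == "lok-atl") c(50, 50) else c(50, 12.5)
  if (is.null(sample_weight)) sample_weight <- average_tablet_weight
  if (is.null(dilution_factor))
    dilution_factor <- if (preset == "lok-atl") 25 else 62.5
  stopifnot(length(label_claims) == length(models),
            average_tablet_weight > 0, sample_weight > 0,
            stock_volume > 0, dilution_factor >= 1)
  # mg of each drug in the weighed powder -> stock ug/ml -> measured ug/ml
  drug_mg <- label_claims * sample_weight / average_tablet_weight
  stock_ug_ml <- drug_mg * 1000 / stock_volume
  true_conc <- stock_ug_ml / dilution_factor
  .with_seed(noise$seed, {
    meas <- t(vapply(seq_len(n), function(i)
      .measure_mixture(models, true_conc, m$wavelengths,
                       noise$absorbance_sd), numeric(2)))
    colnames(meas) <- format(m$wavelengths, trim = TRUE)
    structure(
      list(measurements = meas,
           true_concentrations_ug_per_ml = stats::setNames(true_conc, m$components),
           label_claims = stats::setNames(label_claims, m$components),
           average_tablet_weight = average_tablet_weight,
           sample_weight = sample_weight, stock_volume = stock_volume,
           dilution_factor = dilution_factor, preset = preset,
           wavelengths = m$wavelengths, components = m$components),
      class = "assay_samples")
  })
}

#' Solve and summarize replicate assay samples
#'
#' Runs every replicate of [generate_assay_samples()] through the solver
#' and back-calculates mg/tablet against the label claim via
#' [assay_tablets()].
#'
#' @param samples An `assay_samples` object.
#' @param m The matching [vierordt_preset()] matrix; defaults to the one
#'   the samples were generated for.
#' @return A named list of `assay_report`s, one per component.
#' @export
analyze_assay_samples <- function(samples, m = vierordt_preset(samples$preset)) {
  stopifnot(inherits(samples, "assay_samples"))
  conc <- apply(samples$measurements, 1, function(a)
    solve_two_component(m, a)$concentrations_ug_per_ml)
  reports <- lapply(seq_along(samples$components), function(k)
    assay_tablets(solved_concentrations = conc[k, ],
                  dilution_factor = samples$dilution_factor,
                  stock_volume = samples$stock_volume,
                  sample_weight = samples$sample_weight,
                  average_tablet_weight = samples$average_tablet_weight,
                  label_claim = samples$label_claims[[k]],
                  analyte = samples$components[k]))
  stats::setNames(reports, samples$components)
}
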