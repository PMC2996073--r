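test_that("preset band models hit the published absorptivity anchors", {
  anchors <- list(
    LOK = c("251.6" = 320.25, "224.2" = 661.75),
    ATL = c("224.2" = 866.75, "251.6" = 8.1, "271.6" = 106.0),
    HCTZ = c("224.2" = 1288, "271.6" = 720))
  mods <- preset_band_models()
  for (nm in names(anchors)) {
    wl <- as.numeric(names(anchors[[nm]]))
    got <- eval_band_model(mods[[nm]], wl)
    expect_equal(got, unname(anchors[[nm]]), tolerance = 0.005)
  }
  atl_la <- preset_band_models(atl_variant = "lok-atl")$ATL
  expect_equal(eval_band_model(atl_la, c(224.2, 251.6)), c(380.50, 8.1),
               tolerance = 0.005)
  # all band heights are physical (non-negative)
  for (md in c(mods, list(atl_la)))
    expect_true(all(md$heights >= 0))
})

test_that("band models place the analytical maxima correctly", {
  mods <- preset_band_models()
  atl <- simulate_pure_spectrum(mods$ATL, 10, noise_model(0))
  expect_equal(find_lambda_max(atl), 224.2, tolerance = 0.1)
  lok <- simulate_pure_spectrum(mods$LOK, 20, noise_model(0))
  expect_equal(find_lambda_max(lok, c(235, 270)), 251.6, tolerance = 0.1)
  hctz <- simulate_pure_spectrum(mods$HCTZ, 10, noise_model(0))
  expect_equal(find_lambda_max(hctz, c(250, 300)), 271.6, tolerance = 0.1)
})

test_that("pure-spectrum simulation is linear, seeded and validated", {
  mods <- preset_band_models()
  zero <- simulate_pure_spectrum(mods$ATL, 0, noise_model(0))
  expect_true(all(zero$absorbances == 0))
  s1 <- simulate_pure_spectrum(mods$ATL, 10, noise_model(0.002, seed = 101))
  s2 <- simulate_pure_spectrum(mods$ATL, 10, noise_model(0.002, seed = 101))
  expect_identical(s1$absorbances, s2$absorbances)
  s3 <- simulate_pure_spectrum(mods$ATL, 10, noise_model(0.002, seed = 102))
  expect_false(identical(s1$absorbances, s3$absorbances))
  a1 <- simulate_pure_spectrum(mods$ATL, 5, noise_model(0))
  a2 <- simulate_pure_spectrum(mods$ATL, 10, noise_model(0))
  expect_equal(a2$absorbances, 2 * a1$absorbances, tolerance = 1e-12)
  expect_error(simulate_pure_spectrum(mods$ATL, -1, noise_model(0)), ">= 0")
})

test_that("noiseless mixtures are exactly additive (Beer-Lambert)", {
  mods <- .scenario_models("lok-atl")
  mix <- simulate_mixture_spectrum(mods, c(20, 20), noise_model(0))
  lok <- simulate_pure_spectrum(mods$LOK, 20, noise_model(0))
  atl <- simulate_pure_spectrum(mods$ATL, 20, noise_model(0))
  expect_identical(mix$absorbances, lok$absorbances + atl$absorbances)
  # single-component "mixture" equals the pure simulation
  one <- simulate_mixture_spectrum(mods["LOK"], 20, noise_model(0))
  expect_identical(one$absorbances, lok$absorbances)
  allzero <- simulate_mixture_spectrum(mods, c(0, 0), noise_model(0))
  expect_true(all(allzero$absorbances == 0))
  expect_error(simulate_mixture_spectrum(mods, 20, noise_model(0)),
               "one concentration per")
})

test_that("mixture readings at analytical wavelengths match the matrix forward model", {
  m <- vierordt_preset("lok-atl")
  mix <- simulate_mixture_spectrum(.scenario_models("lok-atl"), c(20, 20),
                                   noise_model(0))
  expect_equal(absorbance_at(mix, m$wavelengths),
               as.numeric(m$entries %*% c(0.002, 0.002)), tolerance = 1e-3)
  m2 <- vierordt_preset("atl-hctz")
  mix2 <- simulate_mixture_spectrum(.scenario_models("atl-hctz"), c(8, 2),
                                    noise_model(0))
  expect_equal(absorbance_at(mix2, m2$wavelengths),
               as.numeric(m2$entries %*% c(8e-4, 2e-4)), tolerance = 1e-3)
})

test_that("calibration series generation is collinear, seeded and warned", {
  mods <- preset_band_models()
  conc <- seq(2, 12, by = 2)
  series <- generate_calibration_series(mods$ATL, 224.20, conc, noise_model(0))
  cv <- fit_beers_law(series$concentration, series$absorbance)
  expect_equal(cv$slope, 866.75e-4, tolerance = 1e-3)
  expect_equal(cv$correlation, 1, tolerance = 1e-9)
  expect_equal(nrow(generate_calibration_series(mods$ATL, 224.20, numeric(0),
                                                noise_model(0))), 0L)
  s1 <- generate_calibration_series(mods$ATL, 224.20, conc,
                                    noise_model(0.002, seed = 7))
  s2 <- generate_calibration_series(mods$ATL, 224.20, conc,
                                    noise_model(0.002, seed = 7))
  expect_identical(s1$absorbance, s2$absorbance)
  expect_warning(
    generate_calibration_series(mods$ATL, 224.20, c(2, 20), noise_model(0),
                                beers_range = c(2, 12)),
    "outside")
})

test_that("recovery experiments have the three-level triplicate structure", {
  ex <- generate_recovery_experiment("lok-atl",
                                     noise = noise_model(0.002, seed = 1))
  expect_length(ex, 3)
  expect_equal(vapply(ex, `[[`, numeric(1), "level_percent"), c(80, 100, 120))
  expect_equal(unname(ex[[1]]$added), c(16, 16))
  expect_equal(unname(ex[[3]]$added), c(24, 24))
  expect_equal(dim(ex[[1]]$unspiked), c(3L, 2L))
  expect_equal(dim(ex[[1]]$spiked), c(3L, 2L))
  ex2 <- generate_recovery_experiment("atl-hctz",
                                      noise = noise_model(0.002, seed = 1))
  expect_equal(unname(ex2[[1]]$added), c(6.4, 1.6))
  expect_equal(unname(ex2[[3]]$added), c(9.6, 2.4))
  # distinct seeds give distinct replicate noise; same seed reproduces
  ex3 <- generate_recovery_experiment("lok-atl",
                                      noise = noise_model(0.002, seed = 1))
  expect_identical(ex[[1]]$spiked, ex3[[1]]$spiked)
  ex4 <- generate_recovery_experiment("lok-atl",
                                      noise = noise_model(0.002, seed = 2))
  expect_false(identical(ex[[1]]$spiked, ex4[[1]]$spiked))
})

test_that("noiseless recovery is exactly 100% at every level", {
  for (preset in c("lok-atl", "atl-hctz")) {
    ex <- generate_recovery_experiment(preset, noise = noise_model(0))
    res <- analyze_recovery_experiment(ex)
    expect_equal(res$mean_recovery_percent, rep(100, nrow(res)),
                 tolerance = 1e-9)
    expect_equal(res$rsd_percent, rep(0, nrow(res)), tolerance = 1e-9)
  }
})

test_that("noiseless assay returns the label claims exactly", {
  s1 <- generate_assay_samples("lok-atl", noise = noise_model(0))
  expect_equal(unname(s1$true_concentrations_ug_per_ml), c(20, 20))
  r1 <- analyze_assay_samples(s1)
  expect_equal(r1$LOK$amount_found, 50, tolerance = 1e-10)
  expect_equal(r1$ATL$amount_found, 50, tolerance = 1e-10)
  expect_equal(r1$LOK$percent_label_claim, 100, tolerance = 1e-10)
  s2 <- generate_assay_samples("atl-hctz", noise = noise_model(0))
  expect_equal(unname(s2$true_concentrations_ug_per_ml), c(8, 2))
  r2 <- analyze_assay_samples(s2)
  expect_equal(r2$ATL$amount_found, 50, tolerance = 1e-10)
  expect_equal(r2$HCTZ$amount_found, 12.5, tolerance = 1e-10)
  # replicates are distinct under noise but reproducible under one seed
  s3 <- generate_assay_samples("lok-atl", noise = noise_model(0.002, seed = 5))
  expect_equal(nrow(s3$measurements), 5L)
  expect_gt(nrow(unique(s3$measurements)), 1L)
  s4 <- generate_assay_samples("lok-atl", noise = noise_model(0.002, seed = 5))
  expect_identical(s3$measurements, s4$measurements)
})

test_that("simulate-solve parameter recovery is unbiased and tight under noise", {
  for (preset in c("lok-atl", "atl-hctz")) {
    models <- .scenario_models(preset)
    m <- vierordt_preset(preset)
    true_c <- if (preset == "lok-atl") c(20, 20) else c(8, 2)
    # noiseless chain: recovery to numerical precision
    meas0 <- measure_mixture(models, true_c, m$wavelengths, noise_model(0))
    expect_equal(unname(solve_two_component(m, meas0)$concentrations_ug_per_ml),
                 true_c, tolerance = 1e-6)
    # 100 seeded noisy repetitions: bias < 0.5%, RSD < 2%
    est <- sapply(1:100, function(seed) {
      meas <- measure_mixture(models, true_c, m$wavelengths,
                              noise_model(0.002, seed = seed))
      solve_two_component(m, meas)$concentrations_ug_per_ml
    })
    bias <- abs(100 * (rowMeans(est) - true_c) / true_c)
    rsd <- apply(est, 1, percent_rsd)
    expect_true(all(bias < 0.5))
    expect_true(all(rsd < 2))
  }
})
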