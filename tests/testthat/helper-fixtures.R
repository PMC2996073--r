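# Shared fixtures built in code.

# Analytic single-Gaussian absorbance band, the independent oracle for
# interpolation and lambda-max checks.
gaussian_band <- function(wl, center, width, peak) {
  peak * exp(-(wl - center)^2 / (2 * width^2))
}

# Table-style optical constants used across calibration tests:
# slope (AU per ug/ml), intercept (AU), Beer's-law range (ug/ml).
optical_constants <- list(
  LOK  = list(slope = 0.03315, intercept = 0.02127, range = c(5, 30),
              wavelength = 251.60),
  ATL  = list(slope = 0.08503, intercept = 0.01713, range = c(2, 12),
              wavelength = 224.20),
  HCTZ = list(slope = 0.06673, intercept = 0.00657, range = c(2, 14),
              wavelength = 271.60)
)

# A random well-conditioned 2x2 absorptivity matrix (condition < 1e3).
random_well_conditioned_matrix <- function() {
  repeat {
    e <- matrix(stats::runif(4, 1, 1000), 2, 2)
    if (kappa(e, exact = TRUE) < 1e3)
      return(build_matrix(c("X", "Y"), c(230, 260), e))
  }
}
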