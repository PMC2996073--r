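Package: vierordt
Title: Simultaneous-Equation (Vierordt) Quantification of Drug Mixtures from UV Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies multicomponent drug mixtures from UV absorbance
    spectra by the classical simultaneous-equation (Vierordt) method:
    absorbances read at one analytical wavelength per component are solved
    against a matrix of specific absorptivities A(1 g/100 ml, 1 cm).
    Ships the published two-wavelength systems for atenolol combined with
    losartan potassium (251.60/224.20 nm) and with hydrochlorothiazide
    (224.20/271.60 nm), Beer's-law calibration with linearity-range
    enforcement, method-validation statistics (tablet assay against label
    claim, spiked recovery, repeatability and intra/inter-day precision,
    ruggedness), and a seeded synthetic-spectrum generator that emulates
    the pure-component band shapes for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
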