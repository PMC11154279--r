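Package: mrtplan
Title: Treatment Planning and Dose Calculation for Microbeam Radiation
    Therapy at Divergent Kilovoltage X-Ray Sources
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A hybrid dose-calculation engine and treatment-planning toolkit
    for microbeam radiation therapy (MRT) delivered by divergent kilovoltage
    X-ray tubes, such as collimated small-animal irradiators.  The macroscopic
    photon dose is computed on a millimetre voxel grid by a Monte Carlo photon
    transport stage that separates first-interaction (primary) from scattered
    dose; the micrometre-scale lateral microbeam profile in each voxel is then
    reconstructed by convolving the collimator transmittance, a 1D electron
    scatter kernel, and the depth-rescaled focal-spot function of the divergent
    source.  Includes synthetic phantom generators (PMMA slabs, layered mouse
    head), an X-ray tube spectrum model with bundled attenuation tables,
    focal-spot and radiochromic-film calibration fits, plan reports
    (peak/valley dose rates, PVDR, FWHM, irradiation time, positioning
    offsets), and linear-quadratic protraction corrections via the
    Lea-Catcheside factor.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
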