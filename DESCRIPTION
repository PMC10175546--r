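Package: palspheroid
Title: Positron Annihilation Lifetime Decomposition for Tumor Spheroids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for positron annihilation lifetime spectroscopy (PALS) of
    three-dimensional tumor spheroids. Simulates sodium-22 coincidence lifetime
    spectra with known ground truth, decomposes them into para-positronium,
    source (Kapton), free-annihilation and ortho-positronium components by
    constrained Poisson maximum likelihood with an exponentially modified
    Gaussian per-component shape, and compares conditions in units of combined
    standard deviations. Also provides spheroid growth arithmetic (doubling
    time from volume fold change) and radial fluorescence intensity profiling
    of synthetic spheroid images (proliferation rim and necrotic core region
    statistics).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    MASS,
    tools,
    EBImage,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
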