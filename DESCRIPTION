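Package: vhtraits
Title: Hybrid Radiative-Transfer and Heteroscedastic Gaussian-Process Retrieval of Crop Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for hybrid retrieval of crop biophysical and biochemical
    traits (leaf chlorophyll, leaf water, fractional vegetation cover, leaf
    area index and their canopy-level upscalings) from multispectral
    reflectance. Simulates coupled canopy-atmosphere reflectance databases at
    bottom-of-atmosphere and top-of-atmosphere scales, trains variational
    heteroscedastic Gaussian process regression (VHGPR) models per trait, and
    applies them per pixel to multiband imagery with mean, standard deviation
    and coefficient-of-variation uncertainty maps plus k-fold cross-validated
    goodness-of-fit reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    lhs,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
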