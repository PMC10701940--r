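Package: chemocal
Title: Multivariate Calibration and Greenness Assessment for
    Multicomponent UV Spectrophotometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simultaneous spectrophotometric quantitation of
    paracetamol and hyoscine butylbromide in the presence of four toxic
    impurities.  Implements the multilevel multifactor calibration design
    (five levels, six factors, twenty-five mixtures), a synthetic
    Beer-Lambert spectra generator on the 230.0-266.0 nm grid, principal
    component regression, partial least squares (NIPALS PLS2), a linear
    feed-forward network trained by gradient descent, and multivariate
    curve resolution by alternating least squares with non-negativity
    constraints (SIMPLISMA initialisation, fast non-negative least
    squares).  Also provides figures of merit (recovery, RMSEC/RMSEP,
    LOD/LOQ), method-comparison statistics (pooled t, variance-ratio F,
    one-way ANOVA), dosage-form assay arithmetic with standard spiking,
    and analytical-greenness scoring (eco-scale, AGREE, GAPI).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
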