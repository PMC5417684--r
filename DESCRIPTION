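Package: octspeckle
Title: Generalised Gamma Modelling of Corneal OCT Speckle and Its Influence
    on Noncontact Tonometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to study how corneal micro-structure, quantified through
    Generalised Gamma (GG) statistics of optical coherence tomography (OCT)
    speckle, and ocular biometry relate to intraocular pressure (IOP) measured
    by noncontact tonometry. Provides the GG distribution (density, CDF,
    quantiles, random generation), maximum-likelihood fitting of GG parameters
    to linear-intensity speckle samples, corneal B-scan layer segmentation and
    stromal region-of-interest extraction, a synthetic B-scan phantom and
    cohort simulator for fully reproducible testing, and the cohort-level
    statistics: simple regressions with confidence bands, a power-based sample
    size formula, median-split group comparisons (Wilcoxon rank-sum,
    two-sample Kolmogorov-Smirnov contrast of group-level GG densities) and
    forward stepwise regression yielding a structural model of intraocular
    pressure. A command-line interface ties simulation, image processing,
    fitting and statistics into reproducible end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    grDevices,
    graphics,
    utils,
    tools,
    jsonlite,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    readxl,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
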