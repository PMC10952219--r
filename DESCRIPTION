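Package: wellshear
Title: Wall Shear Stress Metrics for Swirling-Well Cell Culture Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis of the wall shear stress (WSS) experienced by cells
    cultured in circular wells on an orbital shaker ("swirling well" models).
    Provides dimensionless characterization of well/orbit/fluid configurations
    (eccentricity, forcing, shallowness, Reynolds, Bond and Weber numbers),
    the seven established WSS metrics (TAWSS, MagMeanWSS, OSI, transWSS, CFI,
    transWSSmin, CFImin) and four characteristic directions computed from
    vector time series, polar-locus construction with ellipse fitting and
    Shape Index, radial profiles and 2-D metric maps, and a synthetic
    flow-field generator that emulates the flow regimes produced by
    computational fluid dynamics of these wells so the whole analysis can be
    exercised without a flow solver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
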