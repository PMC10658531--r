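Package: eafadapt
Title: Personalized Adapter Design for Enteroatmospheric Fistula Management
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing patient-personalized enteroatmospheric-fistula
    adapters from structured-light 3D scans of open abdominal wounds. The
    pipeline covers point-cloud quality control (the 400,000-point re-scan
    gate), 2.5-D surface reconstruction, wound and fistula morphometry,
    parametric offset/loft ring-solid construction with STL export, a
    synthetic wound phantom generator with analytic ground truth for
    validation, and reproduction of the clinical outcome statistics
    (weighted-average quantiles, tie-corrected Wilcoxon signed-rank, paired
    and two-sample t tests) from the packaged per-device and per-patient
    outcome tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    polyclip,
    sp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
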