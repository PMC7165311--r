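Package: fallwarp
Title: Slope-Constrained Dynamic Time Warping for Fall-Signal Re-Enactment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for validating laboratory re-enactments of real-world fall
    events recorded with body-worn triaxial accelerometers. Implements
    slope-constrained asymmetric dynamic time warping (the Sakoe-Chiba
    asymmetricP1 step pattern with slope parameter P = 1) with open-begin and
    open-end subsequence alignment, warping-path backtracking and
    query-normalized Euclidean distances; a six-phase synthetic fall-signal
    simulator (prefall steps, stumble/fall/impact, rest, raising the upper
    body, rest, straightening to standing) with ground-truth phase
    annotations; per-axis iteration reports with percent improvements; phase
    transfer through warping paths; CSV/YAML input and output; and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
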