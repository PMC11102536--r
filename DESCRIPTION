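Package: rotometry
Title: Accuracy of Prescribed Tooth Rotations from Superimposed Dental Models
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies how accurately clear-aligner treatment achieves
    prescribed tooth rotations from triangle-mesh dental models at three
    timepoints (pre-treatment, virtual plan, post-treatment). Provides STL
    input/output with tooth-label and landmark sidecars, rigid
    superimposition by three-point initialisation and iterative-closest-point
    refinement, per-tooth surface best fit for landmark transfer, signed
    rotation angles projected onto the occlusal plane, accuracy and
    performance-error outcome metrics with the 2-degree clinical cutoff, and
    a statistics layer (intraclass correlation, Dahlberg method error,
    normality-gated paired comparisons, accuracy-on-prescription regression,
    paired-t power analysis). A synthetic dental-arch simulator with known
    ground-truth rotations supports end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
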