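Package: helixpsa
Title: Localized Sub-Particle Reconstruction of Flexible Helical Filaments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for determining structures of intrinsically flexible helical
    protein filaments by pseudo single-particle analysis: a ground-truthed
    synthetic cryo-EM data generator (helical lattices of C2 dimers with
    continuous bend/twist heterogeneity, CTF and noise), filament tracing and
    segment extraction, asymmetric (C1) consensus reconstruction by projection
    matching with helical priors, sub-region vector assignment, partial signal
    subtraction and localized sub-particle extraction, independent local
    refinement with gold-standard Fourier shell correlation, and structural
    quantification (helix envelope geometry, active-site spacing, buried
    interface areas, sequence mass, mutation-to-domain mapping). Includes MRC
    2014 and STAR readers/writers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    withr,
    bio3d,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
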