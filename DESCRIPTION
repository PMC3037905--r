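Package: nucurve
Title: Nucleosome Position Prediction from DNA Curvature Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Sequence-based prediction of nucleosome positions from intrinsic
    DNA curvature. Computes per-position helix curvature from dinucleotide
    roll/tilt wedge angles summed with helical phase, matches the resulting
    curvature curve against a canonical nucleosomal curvature template
    (matched filtering), and calls dyad positions from the maximal spectrum
    of a Mexican-hat continuous wavelet transform. Includes evaluation
    statistics (matching-ratio sweeps, interval overlap ratio, hexamer
    occupancy correlation), site-centered analyses (anchored average
    profiles, two-class k-means TSS classification, dinucleotide and
    poly(dA:dT) fraction profiles), JASPAR PWM promoter scanning, and seeded
    synthetic-fixture generators so the whole pipeline is testable without
    genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
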