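Package: fastmuscle
Title: Action-Potential-Driven Muscle-Tendon Model for Fast Skeletal
    Muscle with a Dynamic Calcium-Force Relationship
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Modular Hill-type muscle-tendon model of fast skeletal muscle
    (cat medial gastrocnemius) driven by action-potential trains. Couples
    sarcoplasmic-reticulum calcium kinetics, a dynamically drifting sigmoid
    calcium-activation relationship (midpoint C1 and inverse slope C2), and
    modified Hill-Mashima contractile mechanics with a series elastic
    element. Reproduces sag behaviour of unfused tetani (Types I-IV),
    frequency-dependent isometric force, and length- and velocity-tension
    properties. Includes analytic calibration of the mechanics module from
    printed length-tension and velocity-tension data points, a staged
    derivative-free calibration pipeline with synthetic-trace parameter
    recovery, sag classification and type-map tools, and a command-line
    interface for reproducible simulation runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
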