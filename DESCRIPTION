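Package: golgisim
Title: Self-Organizing Vesicular Transport in a Maturing Golgi Stack
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic kinetic simulator of a Golgi stack undergoing
    cisternal maturation, in which SNAREs and resident enzymes are exchanged
    between cisternae by a single vesicle species. Vesicle loading follows a
    competitive mass-action equilibrium for a shared pool of binding sites,
    fusion of a vesicle with a target compartment is weighted by the products
    of cognate vesicular v-SNARE and cisternal t-SNARE concentrations, and a
    discrete shift event models maturation of the whole stack once per period.
    The package ships figure-style scenario presets (single SNARE pair,
    competing cis/medial/trans enzymes under open or closed endoplasmic
    reticulum boundaries, the full two-pair mammalian configuration, an
    unrestricted-fusion topology, and a long stack), an analytic solver for
    the exponential steady-state SNARE gradient, profile fitting utilities, a
    YAML configuration format, and a small command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
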