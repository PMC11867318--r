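Package: vmbsim
Title: Generalized Lotka-Volterra Simulation of Vaginal Microbiome
    Probiotic Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An in silico framework for the rational design of vaginal
    probiotic therapy. Simulates a four-species generalized Lotka-Volterra
    model of the vaginal microbiome (non-optimal anaerobes, Lactobacillus
    iners, optimal Lactobacillus spp., and a probiotic strain), generates
    virtual patient populations with bacterial vaginosis by Latin Hypercube
    Sampling and analytic fixed-point classification, simulates probiotic
    and antibiotic dosing regimens, classifies community state types with a
    nearest-centroid rule, and provides local sensitivity analysis,
    systematic probiotic strain screening with PLS-DA profiling, and the
    accompanying statistics layer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    lhs,
    stats,
    utils,
    yaml,
    jsonlite,
    mixOmics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
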