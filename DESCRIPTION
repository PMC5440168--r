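Package: flyring
Title: Ring-Attractor Simulation and Analysis of the Fly Head-Direction Circuit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Firing-rate simulation of the E-PG/P-EN recurrent loop of the
    Drosophila central complex as a ring attractor that integrates angular
    velocity, together with the analysis toolchain used to characterize such
    circuits: population-vector bump tracking from ROI fluorescence,
    velocity-transfer and diffusion metrics of the integrator, conjunctive
    (heading x rotation) tuning statistics for single neurons, shuffle-based
    null distributions for tuning indices, and synthetic behavioral, imaging
    and spike-train generators with known ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
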