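Package: coevin
Title: Interface Coevolution, Geometry and Free-Energy Analysis for Chaperone Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing protein-protein interfaces of Hsp70
    chaperone / J-domain cochaperone complexes and for post-processing
    biased-sampling simulations. Provides geometric detectors for
    cross-interface contacts, ion pairs, hydrogen bonds and buried
    hydrophobic surface; WHAM with Monte Carlo bootstrap errors and
    well-tempered metadynamics free-energy reconstruction; and a
    phylogenetic test for coevolving residue pairs across an interface
    based on a pairwise Markov substitution model compared against
    independent evolution by delta-AIC, with a simulation-calibrated
    significance threshold. A synthetic-data module generates trees,
    alignments, toy complexes and biased-sampling time series with known
    ground truth so the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    bio3d,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
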