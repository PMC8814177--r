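Package: abmetab
Title: Agent-Based Spatial Simulation of Metabolic Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An agent-based spatial simulator for metabolic pathways in which
    enzymes, metabolites and enzyme-substrate complexes diffuse as hard spheres
    in an attolitre-scale cytoplasm cube and bind through perception spheres of
    configurable radius. Molecule radii follow from molecular weight and the
    protein partial specific volume, diffusion from the Stokes-Einstein
    relation, and catalysis from a per-reaction automaton whose saturated
    complexes wait the reciprocal of the turnover number before releasing
    products. Includes an SBML importer with pathway adaptation rules, a
    bundled yeast glycolysis network, and observables for concentration time
    series: depletion times, dominant oscillation frequency and synchrony.
    Designed to compare short-range (5-10 Angstrom) and long-range
    electrodynamic (300 Angstrom) interaction regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
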