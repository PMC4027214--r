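Package: dnarmd
Title: NOE-Restrained Refinement and Analysis of DNA Bis-Intercalator Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for solution-structure determination of DNA-ligand
    complexes from NMR distance information: isolated-spin-pair calibration
    of NOESY volumes into bounded distance restraints, construction of
    idealized B-DNA duplexes with intercalation gaps and bis-intercalated
    ligands, restrained molecular dynamics with simulated annealing on a
    simplified force field, helical-parameter and ensemble statistics
    (rise, twist, unwinding, restraint violations, pairwise RMSD), and
    fluorescent-intercalator-displacement binding-isotherm fitting.
    Includes seeded synthetic-data generators (ground-truth complexes,
    NOESY peak lists, FID titrations) so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
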