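Package: quenchbind
Title: Fluorescence Quench Titration Analysis of Ligand-Protein Binding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of ligand-protein interaction spectroscopy built
    around serum-albumin drug binding studies: inner-filter correction and
    Stern-Volmer analysis of fluorescence quench titrations, association
    constants and stoichiometry from the mass-balance-corrected double
    logarithmic isotherm, van't Hoff thermodynamic decomposition, Forster
    resonance energy transfer distance estimation, conformational-change
    metrics (synchronous and excitation-emission-matrix fluorescence,
    circular dichroism mean residue ellipticity, thermal melt recovery),
    and site-marker displacement assays.  A synthetic-data generator
    emulates complete titration experiments with known ground truth so
    every stage of the pipeline can be validated without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
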