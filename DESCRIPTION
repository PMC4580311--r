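Package: xumpflux
Title: Compartmentalized Metabolic Modeling and 13C Flux Analysis of
    Methylotrophic Yeast
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for systems-level analysis of methylotrophic yeast
    (Pichia pastoris / Komagataella) central carbon metabolism. Provides a
    compartmentalized stoichiometric model of the peroxisomal
    xylulose-monophosphate cycle with per-reaction carbon atom maps,
    steady-state 13C label propagation via elementary metabolite units
    (EMU) with a brute-force isotopomer oracle, weighted least-squares
    flux estimation against mass distribution vectors of proteinogenic
    amino acids, chemostat balance calculations (yields, electron
    closure, exact masses), transcript/protein differential-regulation
    calling and co-regulation classification, peptide-level proteome
    filtering with peroxisome-enrichment scoring, and seeded synthetic
    data generators for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    tools,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
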