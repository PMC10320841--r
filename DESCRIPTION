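Package: ternaq
Title: Equilibrium Modelling of Cooperative Ternary Complex Formation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Mass-action equilibrium model for ternary complexes formed by a
    chaperone protein, a small-molecule ligand and a target protein (PROTACs,
    molecular glues and related proximity-inducing compounds). Solves the
    cooperative three-body equilibrium from the two binary dissociation
    constants and the intrinsic cooperativity, inverts total to free ligand
    in closed (biochemical) systems, simulates binding curves with the hook
    effect, extracts model-based EC50s, retrieves intrinsic cooperativity
    from apparent (EC50-shift) cooperativity or observed curves, classifies
    compounds into the bifunctional/molecular-glue taxonomy, and translates
    biochemical potency into predicted cellular target occupancy. All
    concentrations are in nM.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
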