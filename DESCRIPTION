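Package: coilDock
Title: Coiled-Coil Bundle Construction, Rigid-Body Docking and Interface
    Analysis for Divisome Subcomplexes
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds all-atom-backbone coiled-coil bundles of specified
    stoichiometry from sequences and heptad registers using a Crick
    coil-of-coils parameterization, derives empirical residue-pair contact
    potentials from two-chain interface training sets and uses them to rank
    candidate complexes, performs grid-based rigid-body docking of a globular
    partner by FFT shape complementarity with biological distance and
    membrane-orientation restraints, and computes quantitative interface and
    surface descriptors (solvent-accessible surface area, interface residues,
    hydrogen bonds, salt bridges, composition percentages, interaction
    densities, alanine-scan hotspots, charged surface patches) together with a
    stability classification against a mean-stable-complex reference. A
    synthetic-data module generates ideal bundles, decoy sets, toy receptors
    and statistically controlled interface training sets so the whole pipeline
    runs without external inputs. Developed around the periplasmic
    FtsB/FtsL/FtsQ subcomplex of the bacterial divisome.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    Biostrings,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
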