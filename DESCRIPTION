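Package: b16ovasim
Title: Agent-Based Simulation of B16-OVA Melanoma Immunotherapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stochastic agent-based simulator of B16-OVA melanoma progression
    and adoptive immunotherapy (OT-1 CD8 T-cell transfer with or without
    agonist anti-CD137 antibody) on a two-dimensional hexagonal tissue
    lattice.  Specific recognition between cell receptors, antibodies,
    antigen epitopes and peptides uses a fixed-width bit-string repertoire
    with thymic selection and hypermutation.  Tumor growth follows a
    Gompertz law seeded onto the lattice by forward-Euler discretization,
    with fitting utilities for caliper diameter series and a synthetic
    measurement generator.  Includes the six canonical cell and molecule
    interaction rules, chemotaxis-biased movement, an endothelial CD137
    infiltration gate, treatment scheduling for the nine experimental arms,
    and replicate orchestration with fully seeded reproducibility.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
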