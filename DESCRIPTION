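Package: thqche
Title: Analytics for Tetrahydroquinoline Hybrid Cholinesterase Inhibitor Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable analysis pipeline for small-molecule cholinesterase
    inhibitor series built on a tetrahydroquinoline (THQ) scaffold fused to
    isoxazole or isoxazoline rings: molecular-formula mass arithmetic and
    elemental analysis, IC50-based activity analytics (selectivity index,
    free-energy conversion, rule-of-five screening), enzyme-inhibition
    kinetics with mechanism discrimination by corrected AIC, ensemble-docking
    pose clustering with consensus binding-mode selection ranked by
    correlation against experimental free energies, and geometric
    protein-ligand interaction fingerprinting. Includes seeded synthetic-data
    generators with ground-truth sidecars so every stage is testable at desk
    scale without commercial docking or rescoring engines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    jsonlite,
    yaml,
    bio3d,
    ChemmineR
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
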