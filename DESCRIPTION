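Package: bbbfp
Title: Pharmacophore Fingerprints for Blood-Brain-Barrier Permeation Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Standardizes and deduplicates small-molecule libraries, analyses
    Bemis-Murcko scaffolds and their blood-brain-barrier permeation
    probability, and generates three protein-ligand pharmacophore
    fingerprints for permeability modelling: a residue-contact fingerprint
    over the most frequently contacted binding-site residues of docked
    poses, a 9-type geometric interaction fingerprint, and a 39,971-bit
    topological 2-point/3-point ligand pharmacophore fingerprint. Includes
    a stratified cross-validation benchmark (support vector machine, random
    forest, naive Bayes, and a uniform-random baseline) with the usual
    binary classification metric suite, and deterministic synthetic-complex
    generators so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    dplyr,
    e1071,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    bio3d,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
SystemRequirements: Open Babel (obabel on the PATH)
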