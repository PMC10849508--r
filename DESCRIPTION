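Package: dockpharm
Title: Hit Triage and Pharmacology Analytics for Structure-Based Ligand
    Discovery Campaigns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for the quantitative stages of a large-library docking
    campaign and its downstream pharmacology, developed around a
    cannabinoid-receptor agonist discovery workflow. Covers post-docking
    hit triage (physical-property windows, circular-fingerprint Tanimoto
    similarity, greedy leader clustering of score-ranked libraries,
    novelty rejection against known-ligand sets, analog retrieval,
    campaign bookkeeping), geometric pose evaluation (polar-contact
    filters against receptor site atoms and symmetry-corrected ligand
    RMSD by optimal assignment), in vitro pharmacology (four-parameter
    logistic concentration-response fitting, reference normalisation,
    Cheng-Prusoff Ki, BRET standardisation and per-pathway
    relative-efficacy statistics), and in vivo summaries
    (noncompartmental pharmacokinetics with below-quantitation handling,
    therapeutic windows, conditioned-place-preference scores). Seeded
    synthetic-data generators emulate every input so each stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    bio3d,
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
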