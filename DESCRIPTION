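Package: phylopatch
Title: Community Phylogenetics of Patch Colonization and Extinction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing how habitat size and predator presence shape
    the species richness and phylogenetic relatedness of invertebrate
    metacommunities assembled in discrete habitat patches such as bromeliad
    tanks. Implements abundance-weighted and unweighted mean pairwise and
    nearest-taxon distances with standardized effect sizes (NRI/NTI) under a
    seedable taxa-labels permutation null, Faith's phylogenetic diversity,
    species-level response z-score indices for colonization and extinction
    experiments (size preference, predator avoidance, size and predator
    sensitivity) with closed-form and Monte-Carlo nulls, Blomberg's K with
    permutation tests across taxonomic scales, AICc-based ordinary
    least-squares model selection with partial R-squared reporting, and a
    simulator that generates phylogenies, conserved or convergent response
    traits, and survey, colonization-experiment and extinction-experiment
    datasets for calibration and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    S4Vectors,
    SummarizedExperiment,
    lmtest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    picante,
    phytools,
    igraph,
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
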