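Package: evImmunoPCR
Title: Simulation and Quantification for Antibody-DNA Conjugate qPCR Assays on Extracellular Vesicles
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A computable model of immuno-PCR detection of tumor-associated
    extracellular vesicles (EVs) with antibody-DNA conjugates. Provides
    sequence-level tools for the assay's oligonucleotide designs (in-silico
    ligation, primer/probe siting, amplicon extraction), the Poisson/multinomial
    statistics of biotinylated antibody and DNA partitioning over tetravalent
    streptavidin, a seeded generative simulator of EV populations, conjugate
    labeling, bead capture and proximity ligation, a qPCR standard-curve model
    (Ct simulation, fitting, inversion, limit of detection), and the inverse
    quantification chain from measured DNA concentration to antibody and
    antigen-mass concentration with linear uncertainty propagation and digital
    Poisson particle counting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    S4Vectors,
    jsonlite,
    yaml,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
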