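Package: mesonet
Title: Soil Microbial Network Topology and Plant Community Stability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links plant community temporal stability to the topology of soil
    microbial co-occurrence networks in a two-soil mesocosm design. Provides
    plant community descriptors (Shannon diversity, inverse-CV temporal
    stability, invasion impact and developmental trajectories), OTU table
    preparation (filtering, rarefaction, centered log-ratio transform, a
    habitat specialisation index with under-sampling correction, enrichment
    classification), signed co-occurrence network inference by neighborhood
    selection with StARS stability selection, spin-glass clustering of signed
    networks, degree-preserving rewiring null models, a prokaryote-fungal
    cluster coupling statistic, piecewise path models with d-separation
    Fisher's C tests and AICc backward elimination, a grouped relative
    contribution ledger, and a synthetic mesocosm data generator with planted
    ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    igraph,
    jsonlite,
    nlme,
    optparse,
    Rcpp,
    stats,
    tools,
    utils,
    vegan,
    yaml
LinkingTo: Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
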