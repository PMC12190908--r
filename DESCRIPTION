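Package: pertcombi
Title: Drug-Perturbation Proteomics Analysis and Combination-Therapy Nomination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Turns drug-perturbation protein-expression profiles into ranked
    anti-resistance drug-combination candidates and quantifies tested
    combinations by Chou-Talalay combination indices. Provides differential
    response analysis against batch-matched vehicle controls, NetBox-style
    network module detection with a hypergeometric linker statistic,
    over-representation and preranked gene-set enrichment analysis,
    functional (oncogene/tumor-suppressor) scoring of candidate resistance
    mechanisms, median-effect dose-response modelling with combination-index
    computation from checkerboard viability assays, and synthetic-data
    generators with known ground truth for every input kind.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
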