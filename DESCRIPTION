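Package: druglandscape
Title: Genome-Wide Drug-Target and Drug-Signature Network Landscape
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds bipartite drug-gene networks from drug-target binding
    tables and drug-perturbation expression signatures, scores every gene by
    its drug-target degree (KDTN) and drug-sensitive degree (KDSN), partitions
    genes into target-only (DTG), sensitive-only (DSG) and dual (DTSG) sets,
    characterises the heavy-tailed degree distributions (reverse-cumulative
    curves, discrete power-law maximum-likelihood fits), peels each network
    layer into m-cores with the degree constraint on gene nodes, and runs
    hypergeometric over-representation and transcription-factor binding
    frequency analyses against user-supplied GMT libraries. Ships a synthetic
    data generator with planted structure so the whole pipeline is testable
    without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
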