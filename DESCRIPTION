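Package: mhlink
Title: Microbe-Host Protein Interaction Prediction and Network Diffusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts protein-protein interactions between microbial and host
    proteomes from domain-domain and domain-motif evidence, applying
    localization filtering and a steric quality control that rejects motif
    matches outside intrinsically disordered regions or inside globular
    domains. Predicted host receptors are then connected to condition-relevant
    target genes through a directed multilayer network (protein-protein and
    transcriptional-regulatory layers) using restart-based network diffusion
    and min-heat linker selection, followed by signalling-chain enumeration
    with condition-exclusivity and terminal-regulatory-edge filters, and
    hypergeometric over-representation analysis of the resulting model.
    Includes a deterministic synthetic-fixture generator with planted ground
    truth so the whole pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
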