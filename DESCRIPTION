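Package: netmedr
Title: Network Medicine: Disease Modules, Drug Prioritization and
    Empirical Validation on Heterogeneous Biological Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds typed heterogeneous networks of genes, proteins, drugs
    and diseases, mines candidate disease modules on the protein-protein
    interaction layer (Multi-Steiner Trees with a hub penalty, and DIAMOnD
    greedy expansion by hypergeometric connectivity significance),
    prioritizes repurposable drugs against a seed set (TrustRank and
    seed-restricted harmonic closeness on the combined protein-drug layer),
    and validates modules and ranked drug lists with permutation-based
    empirical p-values (DCG, overlap, precision against topology-matched
    mock modules). Ships a synthetic benchmark generator with planted
    modules and ground-truth drugs so the whole pipeline is testable
    without any database download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Matrix,
    jsonlite,
    xml2,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
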