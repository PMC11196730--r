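Package: connectotypes
Title: Theoretical Brain Surgery on Structural Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates anatomically plausible cortical resections on structural
    brain connectomes and measures the resulting decline in global efficiency.
    Enumerates every connected set of physically adjacent parcels within a lobe
    (up to a configurable size), recomputes global efficiency after each virtual
    resection, classifies per-subject stepwise versus non-stepwise decline
    patterns, tabulates cohort-level worst-deletion frequencies, identifies lobe
    epicenters and per-subject connectotypes from early arrival in the
    worst-deletion progression, and scores how well PageRank hub centrality
    predicts the worst deletions. Includes a synthetic connectome cohort
    generator with planted epicenters so every analysis stage can be validated
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
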