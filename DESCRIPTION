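Package: retrofrag
Title: Retrosynthetic Fragmentation and Fragment-Set Enrichment Analysis of Small Molecules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes sets of small molecules into chemically meaningful
    building blocks using SMARTS-encoded bond-cleavage rules (RECAP/BRICS-style
    retrosynthetic fragmentation). An extensive mode enumerates all valid
    fragmentations by finding maximal cliques (Bron-Kerbosch) of a
    bond-compatibility graph, so that every fragment above a minimum heavy-atom
    size is generated. The resulting fragment sets can then be analysed:
    per-molecule frequency distributions, similarity-based clustering of
    fragments with linear-path fingerprints and the Tanimoto coefficient, and
    hypergeometric enrichment of fragments or fragment clusters against a
    background library with Benjamini-Hochberg false-discovery-rate control.
    Includes deterministic toy-library generators with planted enriched
    fragments for validation, and command-line entry points for shell
    pipelines.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineOB,
    igraph,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
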