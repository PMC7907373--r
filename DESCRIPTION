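Package: interolign
Title: Cross-Species Protein Interaction Network Alignment and Interolog Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds, filters and compares species-labeled protein-protein
    interaction networks. Implements seeded subnetwork extraction from
    STRING-style scored edge tables, global protein sequence similarity
    (Needleman-Wunsch) as a biological node-similarity input, one-to-one
    global network alignment by a genetic algorithm and a greedy baseline
    maximizing a blend of edge conservation (S3 or EC) and sequence
    similarity, evaluation against predicted ortholog maps (correct node
    alignments, aligned interactions, interologs), and construction of
    unified and common conserved networks. Includes a duplication-divergence
    generator of paired species networks with planted ortholog truth for
    benchmarking the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
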