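Package: koannot
Title: Embedding-Based KEGG Orthology Annotation of Bacterial Protein
    Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An embedding-gated pipeline for assigning KEGG Orthology (KO)
    identifiers (K numbers) to bacterial protein sequences. A binary
    classifier over protein-sequence embeddings separates KO from non-KO
    sequences; sequences gated as KO receive a K number transferred from
    their Euclidean nearest neighbour in an annotated reference embedding
    set, with ties reported. Includes the dataset-construction rules
    (length filtering, undefined-residue removal, de-duplication with
    annotation-conflict resolution, KO/non-KO length-distribution
    balancing, train/test splitting), a four-way match/unmatch/missed/
    added evaluation framework with pipeline precision/recall/F1, and a
    validation toolkit (TM-score over a residue correspondence with
    Kabsch superposition, Smith-Waterman percent identity). A
    deterministic mock embedder and synthetic fixture generators make
    the whole pipeline testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
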