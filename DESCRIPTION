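Package: tcriso
Title: Isometric Embedding and Fast Clustering of T-Cell Receptor Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Encodes T-cell receptor CDR3 amino-acid sequences as Euclidean
    coordinates by combining a multidimensional-scaling embedding of the
    BLOSUM62 dissimilarity matrix with an orthogonal cyclic-group block
    transformation, so that sequence similarity becomes (near-)isometric
    Euclidean distance. On top of the encoding it provides nearest-neighbor
    centroid pre-clustering, TRBV-gene matching, k-mer guided ungapped
    alignment filtering into final antigen-candidate clusters, querying of
    new repertoire samples against a clustered reference, clustering-quality
    and spike-in evaluation metrics, reference-based repertoire class
    fractions, and a seeded synthetic-repertoire generator with planted
    antigen-specific groups for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    igraph,
    pROC,
    stats,
    utils
Suggests:
    Biostrings,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
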