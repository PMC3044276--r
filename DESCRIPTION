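Package: metafun
Title: Functional and Taxonomic Analysis of Metagenome BLAST Output
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Assigns metagenome and metatranscriptome reads to SEED
    functional roles, to NCBI-style taxa via the lowest-common-ancestor
    algorithm, and to KEGG orthologies and pathways, starting from tabular
    BLAST output. Aggregates per-read assignments into count profiles over
    (possibly multi-labeled) hierarchies, joins profiles across samples,
    and compares samples with ecological distance indices (Goodall,
    Bray-Curtis, Euclidean, Hellinger, chi-square, Kulczynski) and
    UniFrac. Ships a deterministic synthetic-fixture generator with known
    ground truth and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
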