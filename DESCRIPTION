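Package: beetscreen
Type: Package
Title: Community Analysis-Based Screening of Plant Growth-Promoting Bacteria
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for screening candidate plant growth-promoting bacteria
    (PGPB) from combined 16S rRNA gene clone libraries and culture
    collections: pairwise evolutionary distances from aligned sequences,
    furthest-neighbour OTU clustering at a 97% identity threshold, alpha
    diversity statistics (Good's coverage, Chao1, ACE, Shannon, inverse
    Simpson), abundance-weighted UniFrac with principal coordinate
    analysis, rank-level taxonomic composition tables with an exact
    two-library frequency test, a rule-based candidate selection engine
    (phylogenetic novelty, tissue specificity, persistence, abundance and
    curated reference lists), and Welch t-test evaluation of seedling
    inoculation assays.  A synthetic-study generator with planted ground
    truth supports end-to-end validation without access to the deposited
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    phangorn,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    phyloseq,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
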