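Package: pancooc
Title: Pan-Genome Gene-Family Screening by Phenotype Co-Occurrence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-genomics screen linking gene-family content to a
    quantitative phenotype across closely related bacterial genomes. Predicts
    open reading frames by six-frame scanning, groups the translated proteins
    into gene families by normalized Smith-Waterman distance with
    single-linkage clustering, builds the family-by-genome copy-count
    pan-matrix, and screens each family's abundance profile against the
    phenotype (here, maximum NaCl tolerated) with a Pearson co-occurrence
    statistic. Ships a synthetic-genome generator that plants gene families
    with known copy-number patterns so the whole pipeline is testable without
    external downloads, plus an exhaustive pattern-enumeration oracle for the
    statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
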