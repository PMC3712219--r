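Package: spanner
Title: Rank-Flexible Taxonomic Assignment by Pyramid Matching of Homology Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Assigns taxonomy to sequences from their profiles of homology
    matches. Each sequence is represented by an LCA Profile: its best BLAST hit
    per taxon within a bitscore fraction p of the top hit. Query profiles are
    compared with reference profiles built from an all-versus-all search using a
    modified Pyramid Match Kernel over a taxonomy-by-e-value grid, and the lowest
    common ancestor of the best-matching reference profiles' source taxa gives a
    rank-flexible assignment that is robust to lateral gene transfer. Includes
    MEGAN-style lowest-common-ancestor and best-hit baselines, an ordinal-rank
    evaluation framework with leave-one-out taxonomic novelty masking, and a
    synthetic homology-hit simulator so the whole pipeline can be exercised
    without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
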