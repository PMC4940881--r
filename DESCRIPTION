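Package: cufactor
Title: Factorial Transcriptome Analysis of Gene Deletion Responses Under
    Varying Copper Levels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for 2x2 factorial (gene deletion x copper
    level) transcriptome experiments in yeast. Provides per-gene two-way
    ANOVA with fold-change gating and classification of genes into
    deletion-only, copper-only, additive and interaction response groups;
    self-organizing-map clustering of interaction profiles; hypergeometric
    over-representation tests for GO term flat maps and transcription-factor
    regulons with Bonferroni correction; genetic-interaction network
    construction from BioGRID tables with breadth-first distance-shell
    decomposition, shortest-path enumeration and shell-conditioned
    enrichment; housekeeping-gene stability ranking and 2^-ddCt qPCR
    quantification; and a seeded synthetic-data generator with planted
    ground truth for every pipeline input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
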