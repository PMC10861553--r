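Package: airwaykit
Title: Gene-Content Clustering and Community Typing of Airway Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for relating cultured airway bacterial isolates to
    16S rRNA amplicon communities. Clusters isolate genomes by their binary
    KEGG Orthology (KO) gene content (Manhattan distance, complete linkage,
    and an adaptive dynamic tree cut), scores per-cluster KO enrichment with
    Haldane-Anscombe-corrected odds ratios, types communities with a
    from-scratch Dirichlet-multinomial mixture model (EM fitting, model
    selection, congruence testing), prepares OTU tables (read/prevalence
    filtering, biomass-correlation contaminant flagging, rarefaction, alpha
    and beta diversity), maps OTU representative sequences onto isolate 16S
    genes by binned percent identity, and projects community abundances onto
    isolate gene content to estimate per-sample functional potentials.
    Includes seeded synthetic-data generators with known ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    ape,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
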