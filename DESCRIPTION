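Package: nkdriver
Title: Somatic Variant Prioritization and Driver Nomination for NK-Cell
    Leukemia Exomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for tumor-normal whole-exome somatic
    variant data from chronic lymphoproliferative disorder of NK cells
    (CLPD-NK) and related large-granular-lymphocyte leukemias. Merges
    calls from multiple somatic callers (MuTect, MuTect2, Strelka2
    dialects) with coverage gating, applies an ordered
    population-frequency / ClinVar / deleteriousness filter cascade with
    variant-allele-frequency tiering, computes cohort summaries
    (recurrence, VAF heterogeneity, hotspot screening), converts typed
    pathway topologies into a nonredundant mutated-gene meta-network
    integrated with protein-protein interactions, scores putative driver
    genes, and ships a seeded synthetic cohort generator emulating the
    study design for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    igraph,
    jsonlite,
    vcfR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
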