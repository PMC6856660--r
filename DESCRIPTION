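Package: phylosym
Title: Phylogenetic Community Analysis of Host-Associated Microbiota
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of host-associated 16S rRNA amplicon
    surveys: negative-control-based decontamination and rarefaction of OTU
    tables, phylogenetic alpha and beta diversity (Faith's PD, Shannon,
    unweighted and weighted UniFrac), permutation inference on community
    distance matrices (ANOSIM, PERMANOVA with sequential terms, partial
    Mantel), discriminant-taxon and core-microbiota extraction, and
    host-phylogeny congruence testing via UPGMA dendrograms with jackknife
    support, normalized Robinson-Foulds distances against a random-topology
    null, and phylogenetic eigenvector regression. Includes a synthetic
    community generator that emulates a multi-species, multi-locality
    amphibian skin survey with injected contaminants and tunable locality,
    species, microhabitat and phylosymbiosis effects, so every stage of the
    pipeline is verifiable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    picante,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
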