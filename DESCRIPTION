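Package: resorb
Title: Nutrient Resorption and Phylogenetic Signal in Leaf Traits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to analyse leaf nutrient resorption and accumulation in
    plant communities with contrasting sodium-regulation strategies.
    Computes mass-loss-corrected resorption efficiency and resorption
    proficiency for N, P, K, Na, Ca and Mg, leaf functional traits (SLA,
    LDMC, succulence, K/Na), Blomberg's K phylogenetic signal with a
    tip-shuffling permutation test, Felsenstein's phylogenetically
    independent contrasts and their through-origin correlations,
    standardized major axis line fits, one-way ANOVA with compact letter
    displays, PCA of element concentrations, and sequential variance
    partitioning across sites, plant groups and families.  A seeded
    synthetic-data generator produces phylogenies and paired
    green/senesced leaf datasets with known ground truth so that every
    stage of the pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
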