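Package: phylorensch
Title: Phylogenetic Tests of Rensch's Rule and Sexual Size Dimorphism in Eusocial Bees
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Comparative analysis of sexual size dimorphism (SSD) across a
    time-calibrated phylogeny, built around caste-structured taxa such as
    stingless bees (Meliponini) where queens, workers and males can be measured
    separately. Computes the Lovich-Gibbons SSD index from queen and male body
    sizes, Felsenstein's phylogenetic independent contrasts, major-axis
    allometric regressions of contrasts with a test of the isometry null
    (slope = 1, Rensch's rule), and maximum-likelihood ancestral reconstruction
    of a continuous character under Brownian motion with along-branch
    interpolation for painted-tree figures. Includes a synthetic-data module
    (Yule trees, correlated Brownian caste traits, clade-level dimorphism
    reversals) so every stage of the pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape (>= 5.0),
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phytools
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
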