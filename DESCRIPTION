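Package: isarmech
Title: Mechanistic Dissection of Island Species-Area Relationships
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Individual-based rarefaction framework for asking why species
    richness increases with island area. Estimates total (Chao1), rarefied
    (S_n at a common reference sample size) and evenness-weighted (S_PIE)
    diversity per island, regresses each on log island area, partitions
    within-island beta-diversity from plot data, and classifies the island
    species-area relationship as passive sampling, disproportionate effects
    on rare (or rare and common) species, or within-island heterogeneity.
    Includes a synthetic-archipelago generator with known ground-truth
    mechanisms for calibration and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
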