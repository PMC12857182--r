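Package: ectether
Title: Quantification of ecDNA Tethering to Mitotic Chromosomes from
    Fluorescence Microscopy
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for quantifying extrachromosomal
    DNA (ecDNA) behaviour in fluorescence microscopy of cancer cells:
    perimeter-adjacency tether classification of ecDNA connected components
    in prometaphase spreads, chromosome individualization counts, convex-hull
    spread area, metaphase-plate untethering from FISH/DAPI pixel overlap,
    micronuclei content in newly divided daughter-cell pairs, DNA-damage
    focus counting with a minimum-size rule, chromatin-acetylation intensity
    ratios, and the accompanying statistical layer (ANOVA with Tukey HSD,
    chi-squared contingency tests, Bonferroni-corrected t tests, weighted
    clone means, 2^-ddCt fold changes). A seeded synthetic-scene generator
    renders every scene type with per-object ground truth so each metric is
    verifiable by parameter recovery without external image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
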