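Package: cpmr
Title: Colour Pattern Modelling and Dominance Analysis for Butterfly Wings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies whole-wing colour patterns by Colour Pattern
    Modelling (CPM): wing outlines are extracted from standardized
    photographs, colours are categorized into discrete classes (black,
    orange, yellow), and all wings are aligned into a common model space
    by recursive similarity registration to an iteratively refined
    average wing model, defining pixel-level positional homology.  On top
    of the aligned patterns the package estimates genetic dominance at a
    wing-patterning supergene: per-pixel modal patterns per genotype, a
    surface-based heterozygote trait, dominance coefficients per allele
    pair, dominance heat maps, colour hierarchy maps and conformity
    statistics, with permutation tests throughout.  A synthetic wing
    generator with known allele patterns, dominance mechanisms and
    nuisance transforms provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    jsonlite,
    yaml,
    MASS,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
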