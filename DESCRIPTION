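Package: karyophy
Title: Karyotype Morphometrics and Parsimony Phylogenetics for Plant Cytotaxonomy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for the two computational stages of a classical plant
    cytotaxonomy study. The karyotype stage turns replicate metaphase
    arm-length measurements into averaged homolog-pair summaries, relative
    lengths, Levan-style arm-ratio centromere classes, a canonical karyotype
    formula (with satellite and B-chromosome annotations, plus a parser for
    the formula dialects found in the literature), and idiogram data. The
    phylogenetics stage re-implements maximum parsimony from first
    principles: Fitch scoring, exhaustive and heuristic (random-addition plus
    nearest-neighbour-interchange) tree search, nonparametric bootstrap with
    a retention threshold, outgroup rooting, and ITS1/5.8S/ITS2 partitioning.
    A synthetic-data module simulates noisy metaphase measurements and
    Jukes-Cantor sequence evolution so every stage is testable at desk scale.
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
    knitr,
    phangorn,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
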