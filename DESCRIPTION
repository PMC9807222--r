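Package: stemflex
Title: Flexural Mechanics and Tissue Morphometrics of Climbing Plant Stems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reduction of three-point bending tests on young plant stems to
    flexural stiffness and Young's modulus, pixel-based partitioning of labeled
    stem cross-sections into tissue areas and their contributions to the second
    moment of area, and the diameter-class nonparametric statistics
    (Kruskal-Wallis, Dunn's post-hoc with compact letter displays, Spearman rank
    correlation) used to compare stem growth categories in liana trellises. A
    synthetic-data module generates labeled cross-sections and force-deflection
    records with known ground truth so every stage of the pipeline is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
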