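Package: clonedyn
Title: Clonal Fate Dynamics, Morphometrics and Screen Analysis for
    Oncogene-Expressing Epidermis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of progenitor cell fate choice in mouse
    interfollicular epidermis carrying clonal oncogene activation. Scores
    symmetric-renewal, asymmetric and symmetric-differentiation divisions
    from pulse-chase doublet tables and estimates progenitor renewal rates;
    computes clone morphometrics (fitted-ellipse area and perimeter,
    circularity, basal-cell density) and classifies clone cells as edge or
    inner from a Delaunay neighbor graph; simulates clone growth on a
    hexagonal basal-layer lattice under context-dependent fate
    probabilities (renewing edge, differentiating core); and calls gene
    hits from pooled shRNA screen count tables via a negative-binomial
    basal/suprabasal enrichment test with a two-hairpin consistency rule.
    Includes seeded synthetic-data generators so every analysis is
    exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    deldir,
    stats,
    utils
Suggests:
    DESeq2,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
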