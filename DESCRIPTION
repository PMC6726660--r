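Package: connexinCO2
Title: Structural Determinants of CO2 Sensitivity in Beta Connexins
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Annotation and evolutionary analysis of CO2 sensing in the beta
    connexin family. Calls the carbamylation motif (Lys125/Arg104 with an
    unobstructed 123-124 window, human Cx26 numbering) in any connexin
    protein via reference-anchored pairwise alignment; profiles the
    C-terminal tail and its proline restriction; predicts hemichannel and
    gap-junction CO2 phenotypes with an explicit rule engine; reconstructs
    ancestral trait states on a phylogeny by exact minimum-change and Dollo
    parsimony; quantifies codon-level mutational fragility of the motif
    residues; and implements the quantification rules for dye-loading and
    gap-junction dye-transfer assays, including an exact small-sample
    Mann-Whitney test on replicate medians. A synthetic-data module
    generates trait histories, protein families and assay tables with the
    statistical structure the analysis assumes, so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
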