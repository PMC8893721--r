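Package: sigreverse
Title: Signature-Reversion Drug Retrieval with Benchmarking Standards
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Connectivity-mapping toolkit for signature-reversion drug
    retrieval from LINCS-style perturbation profiles. Implements six
    disease-compound matching methods (eXtreme Sum, eXtreme Cosine, eXtreme
    Pearson, eXtreme Spearman, Kolmogorov-Smirnov, and the Reverse Gene
    Expression Score), two drug-retrieval benchmarking standards (DR-AUC and
    DR-ES) with permutation significance, topN and signature-size sweep
    machinery, a multi-level cosine-similarity analysis of cross-cell-line
    perturbation consistency, query-signature construction utilities, and a
    seeded generator of LINCS-like reference sets with planted reversal
    signal for fully offline evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    fgsea,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: GeneExpression, Pharmacogenomics, Software
RoxygenNote: 7.3.3
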