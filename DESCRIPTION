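Package: recurnet
Title: Differential miRNA-Target Correlation Networks and Neural-Network
    Recurrence Prognosis for Prostate Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-cohort recurrence-prognosis analysis for TMPRSS2-ERG-positive
    prostate cancer from miRNA/mRNA count data: TMM/CPM normalization,
    Mann-Whitney differential expression with Benjamini-Hochberg correction and
    direction-consistent cross-cohort intersection, differential miRNA-target
    Spearman correlation with Fisher r-to-z testing and typed interactome
    network assembly, hypergeometric pathway over-representation, a fully
    connected feed-forward neural-network recurrence classifier trained with
    Adam on expression and clinicopathological predictors, classifier quality
    metrics (sensitivity, specificity, Cohen's kappa, precision, ROC/AUC), and
    qPCR delta-CT relative quantification with group-comparison statistics.
    Includes a synthetic-cohort generator with planted ground truth (negative
    binomial marginals, Gaussian-copula correlations, outcome-associated
    clinical covariates, CT tables) so the full pipeline is testable end to end
    without access to the original cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    igraph
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    pROC,
    xml2
Config/testthat/edition: 3
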