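Package: methwas
Title: Tissue-Specific Methylome-Wide Association Analysis from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Trains cis-genetic prediction models of CpG methylation
    (single-tissue elastic net, cross-tissue sparse-group penalized
    regression, and a best-single-mQTL baseline), tests genetically
    predicted methylation against cancer GWAS summary statistics with a
    weighted Z-score statistic, colocalizes methylation and GWAS signals
    with approximate Bayes factors, conditions associations on known GWAS
    index variants using summary-statistic decompositions against an LD
    reference, scans for cis expression quantitative trait methylation
    (eQTM) target genes, and assembles direction-consistent
    CpG-gene-cancer trios. A synthetic-data module generates LD-block
    genotypes, multi-tissue methylation, expression, and GWAS summary
    statistics under named scenarios with recorded ground truth, standing
    in for controlled-access genotype and methylome resources.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    glmnet,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
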