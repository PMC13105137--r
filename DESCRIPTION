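Package: netprs
Title: Network-Annotated Polygenic Risk Scores from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs polygenic risk scores from GWAS summary statistics and a
    reference linkage-disequilibrium panel using an annotation-weighted L1
    penalized regression solved by coordinate descent. SNP-specific penalty
    weights are derived from a signed genotype-phenotype bipartite network
    built from multi-trait GWAS summary statistics (degree and approximate
    betweenness centrality). Includes cross-trait LD score regression for
    relevant-trait selection, summary-statistic-only model tuning and
    evaluation by conditional subsampling of marginal statistics, a
    multi-trait matrix-normal phenotype simulator, and reference PRS
    baselines (clumping+thresholding, summary-statistic lasso, and the
    infinitesimal-model closed form).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
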