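Package: snpmeta
Title: Genetic-Model Odds-Ratio Meta-Analysis for SNP Case-Control Studies
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for meta-analysis of candidate-gene case-control studies
    reporting genotype counts for a biallelic polymorphism. Builds 2x2
    exposure tables under the four standard genetic-model contrasts
    (homozygote, heterozygote, dominant, recessive), computes per-study odds
    ratios with Woolf variances, pools them by Mantel-Haenszel or
    inverse-variance fixed effects and DerSimonian-Laird random effects with
    Cochran's Q heterogeneity assessment, tests control genotypes for
    Hardy-Weinberg equilibrium, and runs subgroup, leave-one-out sensitivity,
    meta-regression, and Egger/Begg publication-bias analyses. Ships the
    19-study MCP-1 -2518A/G cancer-risk data set as a worked fixture and a
    synthetic study generator for parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
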