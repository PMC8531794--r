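Package: snpmeta
Title: Genotype-Level Case-Control Meta-Analysis of SNP Association Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for meta-analysis of case-control genetic-association
    studies reported as genotype counts at a biallelic locus. Builds the
    five classical genetic-model contingency tables (allelic, heterozygous,
    homozygous, dominant, recessive), screens control arms for
    Hardy-Weinberg equilibrium (chi-squared and exact tests), pools odds
    ratios by Mantel-Haenszel fixed effects (Robins-Breslow-Greenland
    variance) or DerSimonian-Laird random effects with a Cochran-Q
    selection rule, and provides leave-one-out sensitivity analysis,
    Egger regression and Begg rank-correlation publication-bias tests,
    funnel-plot coordinates, and a multinomial simulator of synthetic
    case-control genotype studies with known effect sizes. Ships the
    eleven published CXCR2 C1208T cancer case-control studies as a
    worked dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools
Suggests: testthat (>= 3.0.0), metafor, jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
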