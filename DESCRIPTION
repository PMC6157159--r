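Package: famvar
Title: Familiality and Variability Outlier Screening for
    Treatment-Responsive CpG Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements an indirect screen for CpG sites whose methylation
    responds genetically to a drug treatment when direct pre/post comparison
    is confounded by batch: per-site variability (standard deviation) and
    familiality (birth-order-ordered sibling Spearman correlation) are
    estimated in pre- and post-treatment pedigree samples, upper-tail rank
    outliers of the two post-treatment distributions are intersected, and
    sites that were already pre-treatment outliers are excluded. Candidate
    sites are followed up with a cis-window methylation quantitative trait
    locus scan using a variance-component linear mixed model accelerated by
    a one-time spectral decomposition of the pedigree relatedness matrix.
    A synthetic-data module generates pedigrees, gene-dropped genotypes and
    beta-value matrices with planted treatment-responsive effects so that
    every stage of the pipeline can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
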