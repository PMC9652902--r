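Package: bicoss
Title: Bayesian Iterative Conditional Stochastic Search for GWAS
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Genome-wide association analysis under a kinship linear mixed
    model. Iterates a residual-based single-SNP Bayesian screening step with
    posterior-expected false discovery rate control and a Bayesian
    model-selection step (complete enumeration for small candidate sets, a
    genetic algorithm otherwise), conditioning each iteration on the best
    multi-SNP model found so far. Includes single-marker-analysis baselines
    with Bonferroni correction, a synthetic GWAS simulator with LD-block
    genotypes and a VanRaden realized-relationship kinship, evaluation
    metrics (recall, FDR, FPR, F1), PLINK BED/BIM/FAM and delimited-text
    input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: GenomeWideAssociation, Bayesian, SNP, Genetics, Software
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'bicoss-package.R'
    'driver.R'
    'io.R'
    'lmm.R'
    'metrics.R'
    'plink.R'
    'posterior.R'
    'screening.R'
    'search.R'
    'simulate.R'
    'sma.R'
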