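Package: snpdiv
Title: SNP-Array Diversity Analysis for Structured Population Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for population-genetic diversity analysis of diploid
    biallelic SNP panels spanning many populations: genotype quality
    control (duplicate and chromosome filtering, call-rate thresholds,
    sliding-window LD pruning), seeded frequency-based imputation,
    per-population diversity statistics (observed and expected
    heterozygosity, proportion of polymorphic loci), Reynolds coancestry
    distances with neighbor-joining trees, principal component analysis
    with population-averaged scores, and a binomial admixture model
    fitted by EM with cross-validated selection of the number of
    ancestral clusters. Includes a Balding-Nichols simulator of panels
    with known population structure, readers and writers for VCF and
    PLINK text formats, and a config-driven end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    optparse
Config/testthat/edition: 3
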