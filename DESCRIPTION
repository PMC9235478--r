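Package: pleiopolar
Title: Pleiotropic SNP Discovery from Multi-Trait GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Identifies variants shared between two or more traits from
    genome-wide association study (GWAS) summary statistics. Per-variant
    z-scores are harmonized across traits, decorrelated with ZCA-cor
    whitening, and transformed to polar coordinates: the distance r from
    the origin measures the overall effect and is tested against a central
    chi distribution, while the angle to the nearest trait axis measures
    sharedness and is tested against a mean-zero von Mises null whose
    concentration is calibrated by simulation as a function of r. Both
    stages use Storey q-values for false discovery rate control. Includes
    a synthetic summary-statistic generator with known ground truth for
    calibration experiments, positional clumping of shared variants into
    loci, and construction of weighted trait and trait-domain networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
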