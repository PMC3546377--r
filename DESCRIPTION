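Package: mvhet
Title: Heterogeneity Statistics for Multivariate Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits fixed-effects and random-effects multivariate
    meta-analysis and meta-regression models (generalised least squares;
    restricted maximum likelihood or maximum likelihood estimation of the
    between-study covariance matrix, with missing outcomes handled through
    the marginal model) and quantifies the impact of between-study
    heterogeneity. Provides the generalised-variance ratio statistic R and
    its I-squared analogue for all outcomes, any subset, or any linear
    contrast; the scalar multivariate Cochran statistic Q_s with the
    associated H-squared and I-squared; per-outcome I-squared statistics
    based on the marginal between-study variances; and the classical
    univariate Higgins-Thompson statistics. Includes a synthetic-data
    generator for calibration and parameter-recovery studies, long and
    wide CSV readers, and JSON/CSV report serialisation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    yaml,
    optparse
Config/testthat/edition: 3
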