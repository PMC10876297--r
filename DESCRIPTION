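Package: mrscreen
Title: Two-Sample Mendelian Randomization Screening of GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained toolkit for screening many exposures (e.g. blood
    metabolites) against a single outcome with two-sample Mendelian
    randomization on GWAS summary statistics. Covers instrument selection
    (p-value thresholding, greedy LD clumping, per-SNP variance explained and
    F statistics, weak-instrument and outcome-association exclusion), allele
    harmonization with palindrome removal, six causal estimators (Wald ratio,
    inverse-variance weighted, MR-Egger, weighted median, weighted mode,
    simple mode), the MR-PRESSO global/outlier/distortion tests, and a
    sensitivity battery (Cochran Q, Egger intercept, leave-one-out, funnel
    data, Steiger directionality). Includes a synthetic GWAS summary-statistic
    generator with known ground truth so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
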