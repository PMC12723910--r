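Package: forensnp
Title: SNP Genotyping, Identity Likelihood Ratios and Assay Evaluation for
    Degraded Forensic Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating massively parallel sequencing SNP assays on
    highly degraded skeletal samples. Implements threshold-based genotype
    calling from per-site read counts (coverage, allelic balance, quality and
    strand-balance filters), a genotype-likelihood based direct-match
    likelihood ratio computed from per-allele read depths under
    Hardy-Weinberg priors, replicate-consensus calling, pairwise genotype
    concordance and accuracy metrics, sex-aware call rates with ANOVA/Tukey
    and regression comparisons across assays, and a synthetic read-count
    generator that emulates low-coverage, damaged, contaminated forensic
    sequencing data with full ground-truth bookkeeping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
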