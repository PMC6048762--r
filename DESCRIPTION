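Package: sigburden
Title: Mutational-Signature Activities and Germline Burden Association in
    Cancer Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Links germline variation and somatic gene status to somatic
    mutational-signature activities in tumour cohorts. Builds per-sample
    96-channel trinucleotide mutation catalogs from MAF-like tables, fits a
    mixed-membership probabilistic signature model (independent-context or
    free 96-channel parameterization) by expectation-maximization, matches
    fitted signatures to a reference set by cosine similarity, clusters
    samples on signature activities (Ward linkage), calls germline genotypes
    from pileup summaries by alternate-allele coverage-rate rules, computes
    minor-allele-frequency-weighted gene burden scores, and runs an
    association suite: Wilcoxon rank-sum tests on somatic and copy-number
    status, a weighted-kernel variance-component score test on germline
    burden, multivariate linear regression, and Benjamini-Hochberg FDR.
    Includes a fully parameterized synthetic-cohort generator with planted
    truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    ape
Config/testthat/edition: 3
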