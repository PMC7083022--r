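Package: genassoc
Title: Case-Control Candidate-SNP Association Analysis with Inheritance
    Models, Haplotypes and PCR-RFLP Genotype Calling
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for candidate-gene case-control association studies of
    biallelic SNPs: genotype encoding under codominant, dominant, recessive,
    overdominant and allelic inheritance models; odds ratios with Woolf
    confidence intervals and the Gart zero-cell adjustment; Hardy-Weinberg
    equilibrium testing (1-df chi-square and exact conditional test);
    two-locus haplotype frequency estimation by EM with D, D' and r-squared
    linkage-disequilibrium statistics and haplotype case-control association
    against the most common haplotype; case-only clinicopathological subgroup
    association; multiplicative gene-environment interaction by logistic
    regression; virtual PCR-RFLP genotype calling from restriction-fragment
    size patterns; and a synthetic-cohort generator for calibration and
    power checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
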