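Package: ancspec
Title: Ancestral Spectrum Analysis with Population-Specific Variants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Supervised ancestry inference from rare, population-specific
    single nucleotide polymorphisms. Builds panels of SNPs polymorphic in
    exactly one reference population, computes the genetic relationship
    matrix based on population-specific SNPs (GRM-PS) together with its
    expected form and closed-form eigenstructure, and estimates
    per-individual ancestral proportions by projection-based principal
    scores and by the ancestral information statistic, the best linear
    unbiased estimator (BLUE) of the ancestral proportion, with an optional
    maximum likelihood refinement. Includes a seeded generator of synthetic
    reference and admixed genotypes under the binomial rare-allele model,
    plus VCF input and tab-separated panel and result formats.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
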