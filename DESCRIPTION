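Package: polysfs
Title: Site Frequency and Dosage Spectra for Autopolyploid Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Single-site summary statistics for populations of autopolyploid
    organisms: the empirical and expected Site Frequency Spectrum (SFS), Site
    Dosage Spectrum (SDS) and joint Site Frequency/Dosage Spectrum (SFDS);
    unbiased estimators of nucleotide diversity (Watterson, pairwise and
    Zeng-type) that work directly on per-individual read counts from
    high-throughput sequencing without calling allelic dosage; polyploid
    adaptations of Tajima's D and the normalized Fay-Wu H with read-depth
    effective sample sizes; and perturbative models of Hardy-Weinberg
    violations of the dosage distribution (selfing, disomic inheritance,
    dosage-dependent selection) together with their signatures on
    single-individual SFS-based neutrality tests. Includes a neutral
    coalescent-style simulator of dosage genotypes and read counts used as
    the oracle for all estimator properties, plus VCF/TSV ingestion and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
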