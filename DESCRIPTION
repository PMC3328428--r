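Package: sexlinkr
Title: Sex-Linked SNP Detection and Dosage-Compensation Analysis from RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects X/Y-linked SNPs in multi-sample RNA-seq genotype data
    from an inbred XY family by their diagnostic segregation pattern (all
    males heterozygous, all females homozygous for the same allele), with
    read-count based re-genotyping of males to protect weakly expressed Y
    alleles.  Quantifies allele-specific expression of X and Y gene copies
    from allele depths at sex-linked SNPs with library-size normalization
    (E = r/(n*l)) and an RPKM variant, computes Y/X and Xmale/2Xfemale
    expression ratios, and tests for Y expression degeneration and X
    chromosome dosage compensation (Wilcoxon tests, binned dosage profiles
    with bootstrap confidence intervals, X-allele heterozygosity contrasts).
    Includes a fully parameterised synthetic-data generator with ground
    truth, emulating an inbred XY family with per-contig Y degeneration and
    X compensation, for validation and false-positive calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    jsonlite
Config/testthat/edition: 3
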