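Package: cffmix
Title: Fetal Fraction Estimation from Maternal Plasma SNP Allele Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the cell-free fetal DNA (cffDNA) fraction in maternal
    plasma from targeted-sequencing SNP allele counts alone, without fetal or
    parental genotypes. Biallelic SNP loci are classified by maternal-fetal
    genotype combination; boundary lines in (major, minor) count space select
    the effective loci (mother homozygous, fetus heterozygous), each of which
    yields a per-locus fraction 2y/(x+y); the sample estimate is their median.
    A simulation-calibrated per-depth regression corrects the upward bias that
    appears below 100-fold coverage or below a 10% fetal fraction. Includes a
    seeded synthetic allele-count generator, pileup-based allele counting with
    base-quality filtering, an orthogonal chromosome-Y estimator for male
    pregnancies, deviation metrics, and minimum-depth / minimum-SNP sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
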