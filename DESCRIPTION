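Package: msnpasm
Title: Allele-Specific DNA Methylation Detection from Methylation-Sensitive SNP Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Detects cis-regulated allele-specific DNA methylation (ASM) from
    methylation-sensitive SNP array (MSNP) experiments in which genomic DNA (G),
    MSRE-digested DNA (D) and whole-genome-amplified-then-digested control DNA (U)
    are genotyped on the same array. Implements the relative allele score
    RAS = A/(A+B), the per-probe exclusion criteria based on mean signal distances,
    the delta-RAS-bar ASM statistic over heterozygous individuals, the candidate
    extraction funnel around susceptibility genes with monoallelic/biallelic
    (cis vs imprinting) direction classification, allele-specific
    bisulfite-pyrosequencing validation statistics (paired t and exact rank-sum
    tests), genotype-dosage expression regression, and a synthetic-data generator
    with truth tables for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
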