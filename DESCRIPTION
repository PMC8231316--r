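Package: popdiv
Title: SNP-Based Genetic Diversity and Population Structure of Inbred Line Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genetic diversity and population structure analysis for panels of
    inbred lines genotyped at biallelic SNPs, as practised in plant breeding
    programmes. Reads TASSEL HapMap (and VCF) genotype tables into a
    minor-allele dosage matrix, applies standard quality-control filters
    (sample call rate, SNP call rate, minor allele frequency), computes
    per-marker statistics (MAF, observed heterozygosity, polymorphism
    information content) and chromosome-wise distribution summaries, infers
    admixture-model population structure by maximum-likelihood EM over a range
    of K with Evanno delta-K model selection, performs PCA and
    complete-linkage dendrograms, partitions molecular variance (AMOVA) into
    among- and within-group components with PhiPT, permutation tests and the
    haploid number of migrants Nm, and reports per-subpopulation allelic
    pattern indices (Na, Ne, Shannon's I, h, uh, private alleles). Includes a
    Balding-Nichols simulator of wheat-like genotype panels with known
    structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    vegan
Config/testthat/edition: 3
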