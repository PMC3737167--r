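Package: radpopgen
Title: RAD-Seq Population Genomics of Migratory and Resident Ecotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end RAD-seq population-genomics workflow for
    detecting adaptive divergence between two population samples, built
    around a two-ecotype salmonid study design. Provides a synthetic-data
    generator with known truth (Balding-Nichols allele-frequency model,
    read-depth and sequencing-error model, paralogous sequence variants,
    doubled-haploid reference individuals, a linkage map); de novo RAD tag
    stacking and biallelic SNP discovery; read-ratio genotype calling;
    a SNP quality-filter cascade (doubled-haploid PSV screen, heterozygote
    excess, missingness, minor allele frequency, exact Hardy-Weinberg
    test, polymorphic-in-both); per-locus statistics (Nei and
    Weir-Cockerham FST, heterozygosities, private alleles), windowed
    Tajima's D and Watterson's theta; a simulation-based FST outlier test
    conditional on heterozygosity; and genome-scan utilities (Gaussian
    kernel smoothing along a genetic map, EM haplotype inference, D' and
    chromosome-level linkage-disequilibrium summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
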