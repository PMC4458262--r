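Package: gmshap
Title: Two-Locus Recessive Genetic Male Sterility: Simulation, Linkage and
    Haplotype Marker Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for genetic analysis of duplicate-recessive genetic male
    sterility (GMS), as used in hybrid cotton breeding where sterility requires
    homozygous recessive genotypes at both the ms5 (chromosome A12) and ms6
    (chromosome D12) loci. Provides an exact two-locus Mendelian model with
    gamete enumeration and expected segregation ratios, a meiosis and
    breeding-scheme simulator (F2, fertile-by-sterile sibcrosses, selfed
    progenies, and a random-mating diversity panel) with genotyping noise,
    chi-square goodness-of-fit testing of fertile:sterile segregation ratios,
    two-point recombination-fraction estimation by EM for intercross data with
    LOD-based chromosome assignment, a recessive-coded logistic marker scan
    with an exhaustive cross-locus haplotype search ranked by phenotype
    predictability, and application of haplotype rules to new genotypes for
    marker-assisted selection (sterility prediction, per-locus zygosity calls,
    and germplasm allele screening).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
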