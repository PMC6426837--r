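Package: hemiclone
Title: Ghost-Genome Inference for Hybridogenetic (Hemi-Clonal) Lineages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting 'ghost' genomes carried clonally by
    hybridogenetic (hemi-clonal) lineages and for deciding whether a
    rediscovered sexual population is a pure remnant of the ghost ancestor
    or a natural resurrection cross between hemi-clones. Provides a diploid
    genotype container with readers for VCF, DArT-style SNP tables and
    allozyme genotype tables; the standard SNP locus-filtering chain
    (reproducibility, call rate, secondaries, monomorphic loci); per-taxon
    allele profiles with observed heterozygosity, absolute fixed-difference
    counts, Euclidean and Nei (1972) genetic distances; principal
    co-ordinates analysis of individual genotypes with a quantitative
    F1-intermediacy statistic; diagnostic-locus hybridogen classification
    and the genomic fixed-differences resurrection test; and a forward
    simulator of hybridogenesis with known per-individual truth for
    validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
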