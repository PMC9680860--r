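Package: hyborigin
Title: Hybrid-Origin Inference from Species-Diagnostic SNPs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers the pedigree origin of a suspected interspecific hybrid
    from a multi-sample VCF. Extracts biallelic SNPs fixed for opposite
    alleles in two parental species panels, classifies the focal
    individual's genotype at each diagnostic site, fits multinomial
    likelihoods for backcross-generation models (F1, BC1F1, BC2F1, ...),
    paints chromosome-scale ancestry tracks with majority-window smoothing,
    and computes nucleotide diversity and genome-averaged Wright's FST.
    Includes a hybrid-pedigree simulator (Haldane-model meiosis, maternal
    organelle inheritance, genotype error) that provides ground truth for
    every stage, and exports IUPAC-coded SNP alignments for phylogenetic
    network software.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    vcfR,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
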