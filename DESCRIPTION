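Package: snptyper
Title: SNP Typing of Multi-Locus DNA Barcodes for Plant Germplasm Identification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reference-based SNP typing of Sanger-sequenced DNA barcode loci
    for germplasm identification in medicinal plants, with an emphasis on the
    three-species Amomi Fructus (Amomum) system. Provides quality control of
    bidirectional trace reads (trace score, contiguous read length, windowed
    end-trimming), forward/reverse consensus assembly with IUPAC heterozygote
    calling by the secondary-peak rule, SNP calling against a designated
    reference sample, SNP-genotype (ST) assignment, discriminatory-power
    evaluation of barcode-region combinations, UPGMA clustering with cophenetic
    correlation, maximum-parsimony tree search by simulated annealing with
    column bootstrap, and a priority-rule minimum spanning tree over STs with
    group partitioning and founder-genotype ranking. Includes a synthetic panel
    generator that emulates a 29-landrace, three-species study design with
    planted SNPs, heterozygous sites and a mononucleotide-repeat sequencing
    failure mode.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite
Config/testthat/edition: 3
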