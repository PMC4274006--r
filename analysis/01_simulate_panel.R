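#!/usr/bin/env Rscript
# Stage 1 — simulate the study panel.
#
# Generates the default three-species, 29-landrace panel (4 informative
# barcode loci with 35 planted SNPs, plus a mononucleotide-repeat locus that
# emulates trnH-psbA-style sequencing failure) and simulates 2 individuals x
# 2 directions of Sanger-style reads per sample x locus under the default
# trace model (Phred-consistent basecall errors, QV decay, 0.6 secondary-peak
# fraction at heterozygous sites). Writes truth FASTA and reads as
# FASTQ + secondary-peak sidecar.

library(snptyper)

SEED <- 101  # master seed for the whole analysis

truth <- amomum_panel(snptyper:::stage_seed(SEED, "panel"))
print(truth)

reads <- simulate_reads(truth, trace_model(),
                        seed = snptyper:::stage_seed(SEED, "reads"))
cat("simulated", length(reads), "reads\n")

dir.create("results/data", recursive = TRUE, showWarnings = FALSE)
write_panel_fasta(truth, "results/data/truth_fasta")
write_reads_fastq(reads, "results/data/reads.fastq",
                  "results/data/reads.sec.tsv")
write.table(truth$planted_snps, "results/data/planted_snps.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote results/data/{truth_fasta,reads.fastq,reads.sec.tsv,planted_snps.tsv}\n")
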