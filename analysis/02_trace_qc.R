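#!/usr/bin/env Rscript
# Stage 2 — trace quality control.
#
# Reads the simulated traces back from FASTQ + sidecar and applies the QC
# chain: windowed end-trimming (25-base window, QV floor 25, < 3 bad bases),
# trace score (mean post-trim QV) and contiguous read length (longest run of
# windowed QV > 20). A trace passes at TS >= 35 and CRL >= 200 bp. The
# per-region report is the machine twin of a sequencing-success table; expect
# the repeat-mode locus to sit far below the others.

library(snptyper)

reads <- read_reads_fastq("results/data/reads.fastq",
                          "results/data/reads.sec.tsv")
metrics <- do.call(rbind, lapply(reads, trace_metrics))
report <- qc_report(metrics)
print(report, row.names = FALSE)

dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
write.table(metrics[, names(metrics) != "read_id"],
            "results/tables/trace_metrics.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(report, "results/tables/qc_report.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

worst <- report$region[which.min(report$pct_pass)]
cat(sprintf("\nlowest sequencing success: %s at %.1f%% (repeat-interrupted)\n",
            worst, min(report$pct_pass)))
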