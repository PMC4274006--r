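#!/usr/bin/env Rscript
# Stage 4 — trees over SNP genotypes.
#
# Rebuilds the ST-representative profile matrix from the persisted ST
# assignment table, then: UPGMA dendrogram (merge heights = SNP distance / 2)
# with its cophenetic correlation, and a maximum-parsimony topology found by
# simulated annealing over NNI moves, with 200 column-bootstrap replicates.

library(snptyper)

SEED <- 101

st_tab <- read.delim("results/pipeline/st_assignment.tsv",
                     check.names = FALSE)
prof <- as.matrix(st_tab[!duplicated(st_tab$st),
                         !(names(st_tab) %in% c("sample", "st")),
                         drop = FALSE])
rownames(prof) <- paste0("ST", st_tab$st[!duplicated(st_tab$st)])
cat("profile matrix:", nrow(prof), "STs x", ncol(prof), "SNP columns\n")

D <- snp_distance_matrix(prof)
den <- upgma(D)
print(den)

mp <- mp_search(prof, mode = "anneal",
                seed = snptyper:::stage_seed(SEED, "mp"))
supp <- mp_bootstrap(prof, mp$tree, n_reps = 200,
                     seed = snptyper:::stage_seed(SEED, "bootstrap"))
mp$tree$node.label <- as.character(round(supp))
cat(sprintf("maximum parsimony: score %d; %d/%d internal branches with >60%%
bootstrap support (200 replicates)\n", mp$score, sum(supp > 60, na.rm = TRUE),
            length(supp)))

dir.create("results/trees", recursive = TRUE, showWarnings = FALSE)
ape::write.tree(den$phylo, "results/trees/upgma.nwk")
ape::write.tree(mp$tree, "results/trees/mp_bootstrap.nwk")
ape::write.tree(mp$rooted, "results/trees/mp_rooted.nwk")
write.table(data.frame(statistic = c("cophenetic_r", "parsimony_score"),
                       value = c(round(den$cophenetic_r, 4), mp$score)),
            "results/trees/tree_stats.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote results/trees/{upgma.nwk,mp_bootstrap.nwk,mp_rooted.nwk,tree_stats.tsv}\n")
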