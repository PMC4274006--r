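#!/usr/bin/env Rscript
# Stage 5 — minimum spanning tree, grouping and founder ranking.
#
# From the persisted ST assignment: collapse identical profiles into ST
# nodes, build the priority-rule MST (ties resolved towards the included
# node with the most single-SNP variants, weight 10000, then double-SNP
# variants, weight 10), partition STs into groups of >= 2 STs connected by
# edges of <= 2 SNPs, and rank founder-genotype candidates by single-SNP
# neighbour count then node size.

library(snptyper)

st_tab <- read.delim("results/pipeline/st_assignment.tsv",
                     check.names = FALSE)
prof <- as.matrix(st_tab[, !(names(st_tab) %in% c("sample", "st")),
                         drop = FALSE])
rownames(prof) <- st_tab$sample

coll <- collapse_identical(prof)
D <- snp_distance_matrix(coll$profiles)
g <- build_mst(coll$nodes, D)
g <- find_groups(g)
founders <- founder_candidates(g)
print(g)

top <- founders[founders$founder_rank == 1, ]
cat(sprintf("founder candidate: ST%d (%d members, %d single-SNP neighbours)\n",
            top$st[1], top$size[1], top$slv_neighbours[1]))

dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
write.table(g$edges, "results/tables/mst_edges.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
founders$group <- g$groups[as.character(founders$st)]
write.table(founders, "results/tables/mst_nodes.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

# DOT rendering of the MST: solid edges join grouped neighbours (<= 2 SNPs)
dot <- c("graph mst {", "  node [shape=circle];")
for (k in seq_len(nrow(g$nodes))) {
  st <- g$nodes$st[k]
  dot <- c(dot, sprintf('  ST%d [width=%.2f, label="ST%d (%d)"];',
                        st, 0.5 + 0.1 * g$nodes$size[k], st,
                        g$nodes$size[k]))
}
for (k in seq_len(nrow(g$edges))) {
  style <- if (g$edges$weight[k] <= 2) "solid" else "dashed"
  dot <- c(dot, sprintf('  ST%d -- ST%d [label="%d", style=%s];',
                        g$edges$from[k], g$edges$to[k], g$edges$weight[k],
                        style))
}
dot <- c(dot, "}")
writeLines(dot, "results/tables/mst.dot")
cat("wrote results/tables/{mst_edges.tsv,mst_nodes.tsv,mst.dot}\n")
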