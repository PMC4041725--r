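#!/usr/bin/env Rscript
## Tanimoto clustering of the non-trivial T-invariants, the MCTS
## decomposition, the cluster x MCTS coverage table, and the
## clustering-mode sweep (dendrogram cut vs direct pairwise linking, three
## linkages, three thresholds).
##
## Findings to expect: a handful of multi-member clusters collecting the
## pathway variants; MCTS classes that correspond to reaction blocks
## (degradation machinery, transcription programme, Krebs cycle, branches);
## the most covered MCTS is the pVHL degradation block.

library(vhlpn)

dir.create("results", showWarnings = FALSE)

core <- build_core_model()
ti <- classify_trivial(minimal_t_invariants(core$net))

cl <- cluster_invariants(ti, threshold = 0.65, linkage = "average")
print(cl)
cl_df <- data.frame(
  cluster = names(cl$clusters),
  size = lengths(cl$clusters),
  members = vapply(cl$clusters, paste, "", collapse = " ")
)
write.table(cl_df, "results/03_clusters.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

part <- mcts(ti)
print(part)
mcts_df <- data.frame(
  set = names(part$sets),
  size = lengths(part$sets),
  transitions = vapply(part$sets, paste, "", collapse = ", ")
)
write.table(mcts_df, "results/03_mcts.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("singleton transitions:", paste(part$singletons, collapse = ", "), "\n")

ctab <- coverage_table(ti, part, cl)
cat("\nmost covered sets (invariants containing every member):\n")
print(head(ctab[, c("set", "size", "count")], 10), row.names = FALSE)
write.table(ctab, "results/03_coverage_table.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

sweep <- clustering_mode_sweep(ti, thresholds = c(0.5, 0.65, 0.8))
cat("\nclustering-mode sweep:\n")
print(sweep, row.names = FALSE)
write.table(sweep, "results/03_clustering_mode_sweep.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("\nwrote results/03_{clusters,mcts,coverage_table,clustering_mode_sweep}.tsv\n")
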