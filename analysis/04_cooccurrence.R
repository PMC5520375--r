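#!/usr/bin/env Rscript

# Stage 4: deduplicate clock systems and test pairwise factor
# co-occurrence (right-sided Fisher's exact test, BH at FDR 0.01), then
# cluster the factors and export the significance network.

suppressPackageStartupMessages(library(clockmine))

cohort <- read.delim("results/data/presence_cohort.tsv",
                     check.names = FALSE)
pm <- as.matrix(cohort[, -1])
rownames(pm) <- cohort$strain

uniq <- dedup_systems(pm)
cat(sprintf("deduplication: %d systems -> %d unique combinations\n",
            nrow(pm), nrow(uniq)))

res <- cooccurrence_test(uniq, fdr = 0.01)
write.table(res, "results/cooccurrence.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
sig <- res[res$significant, c("factor_i", "factor_j", "p_raw", "p_adj")]
cat(sprintf("tested %d factor pairs; %d significant at FDR 0.01:\n",
            nrow(res), nrow(sig)))
print(sig, row.names = FALSE)

truth <- read.delim("results/data/presence_truth_pairs.tsv")
planted <- paste(pmin(truth$factor_i, truth$factor_j),
                 pmax(truth$factor_i, truth$factor_j))
called <- paste(pmin(sig$factor_i, sig$factor_j),
                pmax(sig$factor_i, sig$factor_j))
cat(sprintf("planted enriched pairs recovered: %d of %d\n",
            sum(planted %in% called), length(planted)))

ord <- cluster_factors(p_adj_matrix(res))
writeLines(ord, "results/factor_clustering_order.txt")

net <- build_network(res, alpha = 0.01)
write_network(net, "results/network_edges.tsv",
              graphml = "results/network.graphml")
cat("network: node degrees\n")
print(net$nodes[net$nodes$degree > 0, ], row.names = FALSE)
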