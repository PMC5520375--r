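#!/usr/bin/env Rscript

# Stage 3: aggregate accepted hits into per-strain clock systems, with
# genus-level similarity summaries, condensed copy-number profiles and
# protein-length distributions.

suppressPackageStartupMessages(library(clockmine))

rbh <- read.delim("results/rbh_pairs.tsv", comment.char = "#")
db <- unlist(lapply(list.files("results/data/proteomes",
                               pattern = "\\.faa$", full.names = TRUE),
                    function(f) read_proteome(f)$sequences))

inv <- build_inventory(rbh)
write.table(inv, "results/inventory.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("inventory: %d strains retained (>= 1 KaiC-family homolog)\n",
            length(unique(inv$strain))))

gs <- genus_mean_similarity(rbh)
write.table(gs, "results/genus_similarity.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("genus summary (ordered by taxon group, then KaiC similarity):\n")
print(head(gs, 8), row.names = FALSE)

prof <- copy_number_profile(inv)
write.table(data.frame(strain = rownames(prof), prof, check.names = FALSE),
            "results/copy_numbers.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
multi <- sum(apply(prof, 1, function(r) any(r %in% c("2", "3", "4", "5",
                                                     ">5"))))
cat(sprintf("copy numbers: %d of %d strains carry multi-copy factors\n",
            multi, nrow(prof)))

recs <- length_records(rbh, db)
write.table(recs, "results/length_records.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
ld <- length_distribution(recs, c("KaiA", "KaiC1"))
write.table(ld$joint, "results/length_joint_KaiA_KaiC1.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("lengths: %d organisms have both KaiA and KaiC1\n",
            length(unique(ld$joint$organism))))
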