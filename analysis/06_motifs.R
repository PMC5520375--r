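#!/usr/bin/env Rscript

# Stage 6: motif-conservation profiling of a simulated KaiC homolog
# family: per-position residue frequencies in reference coordinates for
# the CII Walker A (P-loop), the S/T phosphosites and T426 windows, and
# wildcard-pattern match fractions.

suppressPackageStartupMessages(library(clockmine))

seed <- 20160506
set.seed(seed)

# reference with the canonical anchors at their KaiC-7942 coordinates
ref <- paste0(paste(sample(AA_STANDARD, 200, replace = TRUE),
                    collapse = ""),
              "GATGTGKT",
              paste(sample(AA_STANDARD, 217, replace = TRUE),
                    collapse = ""),
              "T",
              paste(sample(AA_STANDARD, 4, replace = TRUE), collapse = ""),
              "ST",
              paste(sample(AA_STANDARD, 87, replace = TRUE), collapse = ""))

# homologs: 10% point substitutions, fully conserved anchors in half of
# the family to mimic a functionally constrained subgroup
n_rec <- 40
seqs <- vapply(seq_len(n_rec), function(i) {
  ch <- strsplit(ref, "")[[1]]
  flip <- which(runif(length(ch)) < 0.1)
  if (i <= n_rec / 2) {
    flip <- setdiff(flip, c(201:208, 426, 431, 432))
  }
  ch[flip] <- sample(AA_STANDARD, length(flip), replace = TRUE)
  paste(ch, collapse = "")
}, character(1))
names(seqs) <- c("KaiC_ref", sprintf("hom%02d", 2:n_rec))
seqs[["KaiC_ref"]] <- ref

mapping <- map_to_reference(seqs, "KaiC_ref")
wins <- kaic_motif_windows(ref)

pfms <- do.call(rbind, lapply(wins, function(w)
  column_frequencies(seqs, mapping, w)))
write.table(pfms, "results/motif_pfms.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

rep_tab <- motif_report(seqs, mapping, wins, attr(wins, "patterns"))
write.table(rep_tab, "results/motif_report.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("motif conservation summary:\n")
print(rep_tab, row.names = FALSE)
cat("\nhalf the family was simulated with hard-constrained anchors, so\n")
cat("match fractions sit between the constrained (1.0) and free (~0.66)\n")
cat("regimes; per-position frequencies are in results/motif_pfms.tsv\n")
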