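#!/usr/bin/env Rscript

# Stage 1: generate the synthetic study cohort.
#
# Three substrates, each written in the format the downstream stages
# consume:
#   - a proteome collection (12 taxa) with planted clock-factor families
#     at 70% identity plus compositional decoys, for the homology screen;
#   - a presence/absence cohort of clock systems with planted enriched
#     factor pairs, for the co-occurrence analysis;
#   - diurnal expression time series (two replicates sharing one phase
#     program, plus one independent strain), for the rhythm analysis.

suppressPackageStartupMessages(library(clockmine))

seed <- 20160501
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

## proteomes -------------------------------------------------------------
families <- data.frame(
  query_id = c("KaiC1", "KaiC3", "KaiB1", "KaiA", "SasA", "CikA", "PrkE"),
  identity = 70,
  copies   = c(2, 1, 1, 1, 1, 1, 1),
  prevalence = c(1, 0.5, 0.95, 0.7, 0.8, 0.7, 0.6),
  stringsAsFactors = FALSE
)
prot <- simulate_proteomes(12, families, n_decoys = 20, seed = seed)
write_proteomes(prot, file.path(out, "proteomes"), seed = seed)
cat("proteomes:", length(unique(prot$meta$organism)), "taxa,",
    length(prot$db), "proteins,", nrow(prot$truth), "planted members\n")

## clock-system presence cohort ------------------------------------------
prev <- c(KaiA = 0.9, KaiB1 = 0.95, KaiB2 = 0.3, KaiB3 = 0.35,
          KaiC2 = 0.3, KaiC3 = 0.4, Pex = 0.5, LdpA = 0.9, PrkE = 0.6,
          NhtA = 0.5, IrcA = 0.9, CdpA = 0.55, SasA = 0.9, LabA = 0.6,
          LalA = 0.6, CpmA = 0.9, Crm = 0.5, RpaA = 0.95, RpaB = 0.99,
          CikA = 0.9)
enriched <- data.frame(
  factor_i = c("KaiB2", "KaiB3", "PrkE"),
  factor_j = c("KaiC2", "KaiC3", "CdpA"),
  odds_ratio = c(15, 15, 10),
  stringsAsFactors = FALSE
)
systems <- simulate_clock_systems(120, prev, enriched_pairs = enriched,
                                  seed = seed)
write.table(data.frame(strain = rownames(systems$matrix),
                       systems$matrix, check.names = FALSE),
            file.path(out, "presence_cohort.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(enriched, file.path(out, "presence_truth_pairs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("presence cohort: 120 systems x", ncol(systems$matrix), "factors;",
    nrow(enriched), "planted enriched pairs\n")

## expression time series ------------------------------------------------
set.seed(seed)
shared_phases <- runif(400, 0, 24)
shared_amps <- runif(400, 0.5, 2)
mk_dataset <- function(frac, phase_fun, amp_fun, sub_seed) {
  simulate_expression(400, frac_oscillating = frac,
                      phase_dist = phase_fun, amp_dist = amp_fun,
                      noise_sd = 0.3, seed = sub_seed)
}
phase_fun <- function(n) shared_phases[seq_len(n)]
amp_fun <- function(n) shared_amps[seq_len(n)]
rep1 <- mk_dataset(0.3, phase_fun, amp_fun, seed + 1)
rep2 <- mk_dataset(0.3, phase_fun, amp_fun, seed + 2)  # same program
other <- mk_dataset(0.3, function(n) runif(n, 0, 24),
                    function(n) runif(n, 0.5, 2), seed + 3)
write_expression_tsv(rep1, file.path(out, "strainA_rep1.tsv"), seed + 1)
write_expression_tsv(rep2, file.path(out, "strainA_rep2.tsv"), seed + 2)
write_expression_tsv(other, file.path(out, "strainB.tsv"), seed + 3)
cat("expression: 3 datasets, 400 genes each, 12 timepoints (0-44 h)\n")
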