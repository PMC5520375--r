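#!/usr/bin/env Rscript

# Stage 2: reciprocal best-hit screen of the clock-factor queries against
# the simulated proteome collection, reading the FASTA/sidecar files the
# way a real screen would, and scoring recovery against the generator
# truth.

suppressPackageStartupMessages(library(clockmine))

data_dir <- "results/data/proteomes"
stopifnot(dir.exists(data_dir))
dir.create("results", showWarnings = FALSE)

queries <- read_proteome(file.path(data_dir, "queries.faa"))$sequences
meta <- read.delim(file.path(data_dir, "meta.tsv"), comment.char = "#")
fastas <- setdiff(list.files(data_dir, pattern = "\\.faa$",
                             full.names = TRUE),
                  file.path(data_dir, "queries.faa"))
db <- unlist(lapply(fastas, function(f) read_proteome(f)$sequences))

rbh <- rbh_screen(queries, db, meta = meta)
write_hits_tsv(rbh, "results/rbh_pairs.tsv",
               header = "reciprocal best hits, forward e <= 1e-5, reverse e <= 10")

truth <- read.delim(file.path(data_dir, "truth.tsv"), comment.char = "#")
predicted <- unique(paste(rbh$query_id, rbh$subject_id))
planted <- paste(truth$query_id, truth$member_id)
cat(sprintf("screen: %d accepted RBH pairs over %d proteins\n",
            nrow(rbh), length(db)))
cat(sprintf("recovery vs generator truth: precision %.3f, recall %.3f\n",
            mean(predicted %in% planted), mean(planted %in% predicted)))
cat(sprintf("decoys surviving the reciprocal filter: %d\n",
            sum(grepl("^decoy", rbh$subject_id))))
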