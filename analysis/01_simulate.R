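#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study data.
#
# Emulates the study design: 10 skin donors vs 5 liver donors, each
# fractionated (cytosol/microsomes) and separated into 20 gel regions,
# with log-normal intensity noise, observation-level censoring at the
# detection limit, and a protein database whose names span all four
# keyword-selection outcomes. Writes the FASTA database, the ground-truth
# table and one identification TSV per sample under results/simdata/.

suppressPackageStartupMessages(library(xmeprofiler))

out <- "results/simdata"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = 20120726)
db <- generate_database(cfg)
obs <- simulate_samples(db)

write_database_fasta(db$proteins, file.path(out, "database.fasta"))
write.table(db$truth, file.path(out, "ground_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
paths <- write_sample_tables(obs, file.path(out, "samples"))

cat(sprintf("database: %d proteins (%d XME, %d reject-list, %d filtered, %d decoy)\n",
            nrow(db$proteins), sum(db$proteins$category == "xme"),
            sum(db$proteins$category == "reject"),
            sum(db$proteins$category == "filtered"),
            sum(db$proteins$category == "decoy")))
cat(sprintf("observations: %d identified peptides across %d samples\n",
            nrow(obs), length(paths)))
cat(sprintf("censoring: detection limit %g intensity units, sigma %.2f\n",
            cfg$detection_limit, cfg$sigma))
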