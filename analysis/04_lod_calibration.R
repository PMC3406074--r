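#!/usr/bin/env Rscript
# Stage 4: spike-in limit-of-detection calibration and the bounded-ratio
# arithmetic that places undetected proteins in context.
#
# Part A calibrates LODs from simulated spike series and derives
# concentration bounds for the analysed sample mass.
# Part B takes published reference inputs for the CYP panel (spike-in LODs
# in fmol, liver microsomal levels in pmol/mg) and recomputes the bounded
# skin/liver ratios, the minimum fold separation, the activity equivalent
# of the NAT1 detection limit, and the MS-vs-immunoblot sensitivity ratio.
# Writes results/lod/.

suppressPackageStartupMessages(library(xmeprofiler))

out <- "results/lod"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

## Part A: synthetic spike series ------------------------------------------
cfg <- sim_config(seed = 20120726, sigma = 0)
amounts <- c(0.5, 1.0, 1.5, 2.0, 3.0, 6.0)
panel <- list(
  "monooxygenase alpha" = cfg$detection_limit / c(1.0, 1.5, 3.0, 6.0),
  "monooxygenase beta"  = cfg$detection_limit / c(2.0, 3.0, 6.0, 12.0),
  "monooxygenase gamma" = cfg$detection_limit / c(1.0, 1.0, 2.0, 4.0))
rows <- list()
for (analyte in names(panel)) {
  s <- generate_spike_series(analyte, amounts, cfg,
                             responses = panel[[analyte]])
  rows[[analyte]] <- lod_report(s, analyzed_mg = 0.013,
                                comparator_pmol_per_mg = 50)
}
synthetic <- do.call(rbind, rows)
write.table(synthetic, file.path(out, "synthetic_lod_reports.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("synthetic spike-in panel (0.013 mg analysed, comparator 50 pmol/mg):\n")
print(synthetic, row.names = FALSE)

## Part B: published reference panel ---------------------------------------
cyp <- data.frame(
  analyte = c("CYP1A1", "CYP1A2", "CYP2E1", "CYP3A4", "CYP3A5"),
  lod_fmol = c(1.5, 2.0, 1.5, 3.0, 1.0),
  skin_bound = c(0.11, 0.16, 0.11, 0.23, 0.08),   # pmol/mg upper bounds
  liver_level = c(NA, 50, 35, 105, 25),           # pmol/mg measured
  stringsAsFactors = FALSE)
cyp$relative_bound <- mapply(relative_bound, cyp$skin_bound,
                             cyp$liver_level)
write.table(cyp, file.path(out, "cyp_reference_panel.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nCYP reference panel with recomputed bounded ratios:\n")
print(cyp, row.names = FALSE)

sep <- min_fold_separation(cyp$skin_bound, cyp$liver_level)
cat(sprintf("\nminimum liver/skin fold separation: %.1f (%s)\n",
            sep$min_fold, sep$rendered))

nat1 <- activity_equivalent(3, 8.62)   # pmol/mg LOD x nmol/min/pmol
cat(sprintf("NAT1 LOD activity equivalent: %.1f nmol/min/mg\n", nat1))

sens <- sensitivity_ratio(2.5, 0.1)    # immunoblot vs MS LOD, pmol/mg
cat(sprintf("MS over immunoblot sensitivity: %.0f-fold\n", sens))

gst <- signif_away(753 / 91, 1)        # liver vs skin GST activity
cat(sprintf("liver/skin GST activity ratio: ~%g-fold\n", gst))

summary <- data.frame(
  quantity = c("min_fold_separation", "nat1_activity_equivalent",
               "ms_vs_immunoblot_sensitivity", "gst_activity_ratio"),
  value = c(sep$min_fold, nat1, sens, gst))
write.table(summary, file.path(out, "worked_examples.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
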