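#!/usr/bin/env Rscript
# Stage 1: simulate the study inputs.
#
# Generates the default synthetic single-cell dataset (3000 cells, 1000
# genes, 3 terminal states at proportions 0.40/0.35/0.25, 100 regulons of
# which 10 per state are planted state-specific), the per-fate fate-driver
# table (80% of each planted program emitted as sub-0.05-FDR drivers), and
# a 400-patient bulk cohort in which the fate2 program carries a planted
# log-hazard of 0.6. Everything is written as plain-text exchange formats
# under results/data/ so the later stages run from files, as they would on
# real data.

suppressPackageStartupMessages(library(regfate))

seed <- 1L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

design <- synthetic_design(seed = seed)
sc <- generate_single_cell_dataset(design)
drivers <- generate_fate_drivers(sc$truth, sc$regulons,
                                 overlap_fraction = design$driver_overlap_fraction,
                                 seed = seed + 1L)
cohort <- generate_survival_cohort(400L,
                                   sc$truth$state_specific_regulons$fate2,
                                   beta = 0.6, censoring_rate = 0.3,
                                   seed = seed + 2L)

write_expression_mtx(sc$expression, file.path(out, "expression"))
utils::write.table(sc$cells, file.path(out, "cells.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
write_gmt(sc$regulons, file.path(out, "regulons.gmt"))
utils::write.table(drivers, file.path(out, "drivers.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(cohort$expression, file.path(out, "cohort_expression.tsv"),
                   sep = "\t", quote = FALSE, col.names = NA)
utils::write.table(cohort$survival, file.path(out, "cohort_survival.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
truth_tab <- data.frame(
  regulon = unlist(sc$truth$state_specific_regulons, use.names = FALSE),
  state = rep(names(sc$truth$state_specific_regulons),
              lengths(sc$truth$state_specific_regulons)),
  hub = unlist(sc$truth$state_specific_regulons, use.names = FALSE) %in%
    unlist(sc$truth$hub_tfs))
utils::write.table(truth_tab, "results/ground_truth.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat(sprintf("cells: %d  genes: %d  regulons: %d (planted %d)\n",
            nrow(sc$expression), ncol(sc$expression), length(sc$regulons),
            length(unlist(sc$truth$state_specific_regulons))))
cat(sprintf("drivers: %d rows (%d below FDR 0.05)\n",
            nrow(drivers), sum(drivers$fdr < 0.05)))
cat(sprintf("cohort: %d patients, %d events\n",
            nrow(cohort$survival), sum(cohort$survival$event)))
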