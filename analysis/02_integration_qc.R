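#!/usr/bin/env Rscript
# Stage 2: integration quality metrics.
#
# For every cell, the 30 nearest neighbours in the 2-D embedding are found
# and two neighbourhood fractions computed: the batch mixing score (share of
# neighbours from a different sample; 0.75 is the well-mixed expectation for
# 4 equal samples) and the tissue separation score (share of neighbours of a
# different tissue type; near 0 inside a tight tissue blob).

suppressPackageStartupMessages(library(regfate))

cells <- utils::read.delim("results/data/cells.tsv", stringsAsFactors = FALSE)
g <- knn_neighbors(as.matrix(cells[, c("emb1", "emb2")]), k = 30)
cells$batch_mixing <- batch_mixing_score(g, cells$sample)
cells$tissue_separation <- tissue_separation_score(g, cells$tissue)

utils::write.table(cells, "results/cells_qc.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)

cat(sprintf("mean batch mixing: %.3f (well-mixed expectation 0.75)\n",
            mean(cells$batch_mixing)))
bytissue <- tapply(cells$tissue_separation, cells$tissue, mean)
cat("mean tissue separation by tissue:\n")
print(round(bytissue, 4))
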