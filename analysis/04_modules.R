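#!/usr/bin/env Rscript
# Stage 4: co-activity architecture.
#
# The connection specificity index is computed for every regulon pair from
# the activity matrix and the regulons cut into 7 modules by average-linkage
# clustering on 1 - CSI. The block structure is summarized by the mean CSI
# within versus between modules.

suppressPackageStartupMessages(library(regfate))

act_df <- utils::read.delim("results/activity_matrix.tsv", check.names = FALSE)
activity <- as.matrix(act_df[, -1])
rownames(activity) <- act_df$cell

keep <- apply(activity, 2, function(a) !anyNA(a) && stats::var(a) > 0)
if (any(!keep))
  cat(sprintf("dropping %d constant/unscored regulon column(s)\n", sum(!keep)))
activity <- activity[, keep]

csi <- compute_csi(activity)
modules <- cluster_modules(csi, 7)

utils::write.table(data.frame(regulon = rownames(csi), csi,
                              check.names = FALSE),
                   "results/csi_matrix.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
utils::write.table(data.frame(regulon = names(modules),
                              module = sprintf("Module %d",
                                               as.integer(modules))),
                   "results/regulon_modules.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)

cat("module sizes:\n")
print(table(sprintf("Module %d", as.integer(modules))))
same <- outer(modules, modules, "==") & upper.tri(csi)
diff <- outer(modules, modules, "!=") & upper.tri(csi)
cat(sprintf("mean CSI within modules: %.3f; between modules: %.3f\n",
            mean(csi[same]), mean(csi[diff])))
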