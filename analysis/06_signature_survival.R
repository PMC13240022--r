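#!/usr/bin/env Rscript
# Stage 6: patient-level signature and survival association.
#
# The proliferative-state (fate2) signature is the mean gene-wise z-score of
# the fate2 network's core TFs across the bulk cohort. Patients are split at
# score quartiles; Q4 is compared with Q1 by the log-rank test, and the
# z-scaled score is entered into univariable and stage/age-adjusted Cox
# models. Stage association is checked with a Kruskal-Wallis test.

suppressPackageStartupMessages(library(regfate))

expr <- as.matrix(utils::read.delim("results/data/cohort_expression.tsv",
                                    row.names = 1, check.names = FALSE))
surv <- utils::read.delim("results/data/cohort_survival.tsv",
                          stringsAsFactors = FALSE)
nodes <- utils::read.delim("results/network_fate2_nodes.tsv",
                           stringsAsFactors = FALSE)
sig_genes <- intersect(nodes$node[nodes$kind == "TF"], rownames(expr))
cat(sprintf("signature: %d TFs (%s...)\n", length(sig_genes),
            paste(utils::head(sig_genes, 4), collapse = ", ")))

scores <- signature_score(expr, sig_genes)
qt <- stratify_quartiles(scores)
utils::write.table(data.frame(patient = names(scores), score = scores,
                              quartile = as.character(qt)),
                   "results/signature_scores.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)

q41 <- qt %in% c("Q1", "Q4")
lr <- logrank_test(surv$time[q41], surv$event[q41], droplevels(qt[q41]))
cat(sprintf("Q4 vs Q1 log-rank: chi-square %.2f, p = %.3g\n",
            lr$statistic, lr$p.value))

z <- (scores - mean(scores)) / sqrt(mean((scores - mean(scores))^2))
uni <- cox_ph_fit(surv$time, surv$event, data.frame(signature = z))
multi <- cox_ph_fit(surv$time, surv$event,
                    data.frame(signature = z, stage = factor(surv$stage),
                               age = surv$age))
tab <- rbind(data.frame(endpoint = "OS", model = "Univariate", uni),
             data.frame(endpoint = "OS", model = "Multivariate", multi))
utils::write.table(tab, "results/survival_summary.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("univariable HR per SD of signature: %.2f (95%% CI %.2f-%.2f, p = %.3g)\n",
            uni$hr[1], uni$ci_lower[1], uni$ci_upper[1], uni$p[1]))
cat(sprintf("stage/age-adjusted HR: %.2f (p = %.3g)\n",
            multi$hr[1], multi$p[1]))

ka <- stage_association(scores, surv$stage)
cat(sprintf("signature vs stage (Kruskal-Wallis): chi-square %.2f, p = %.3g\n",
            ka$statistic, ka$p.value))
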