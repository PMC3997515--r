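#!/usr/bin/env Rscript
# Stage 3: the regulated gene set. Empirical-Bayes moderated t-statistics
# for each signal-addition treatment vs control on the quantile-normalized
# values; a gene is "regulated" when BH-FDR < 0.05 in at least one of the
# three contrasts.
suppressPackageStartupMessages(library(combsig))

norm <- read_expression_tsv("results/normalized.tsv")
design <- read_design_tsv("results/data/design.tsv")

fit <- ebayes_moderate(fit_group_means(norm, design))
reg <- select_regulated(fit, alpha = 0.05)
write_table_tsv(reg$table, "results/diffexpr.tsv")
writeLines(reg$gene_ids, "results/regulated_genes.txt")

cat(sprintf("variance moderation: d0 = %.3g, s0^2 = %.4g\n", fit$d0, fit$s0sq))
cat(sprintf("regulated genes (FDR < 0.05, union of 3 contrasts): %d of %d\n",
            length(reg$gene_ids), nrow(norm)))
print(table(reg$table$contrasts[reg$table$regulated]))
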