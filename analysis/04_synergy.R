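#!/usr/bin/env Rscript
# Stage 4: the combinatorial-response test. For each regulated gene, the
# squared deviance of the combined-treatment effect from the sum of the
# single-signal effects is ranked against a permutation null pooled across
# genes (10,000 permutations per gene), Holm-corrected, and the count of
# sub-threshold genes is referred to an exact binomial enrichment test.
suppressPackageStartupMessages(library(combsig))

z <- read_expression_tsv("results/standardized.tsv")
design <- read_design_tsv("results/data/design.tsv")
regulated <- readLines("results/regulated_genes.txt")
regulated <- intersect(regulated, rownames(z))

res <- synergy_test(z, design, genes = regulated,
                    B = 10000, mode = "pooled", seed = 104729, alpha = 0.05)
write_table_tsv(res$table, "results/synergy.tsv")
write_table_tsv(fig2_table(res$table), "results/fig2.tsv")
jsonlite::write_json(unclass(res$enrichment), "results/enrichment.json",
                     auto_unbox = TRUE, digits = NA)
pdf("results/fig2.pdf", width = 7, height = 4); plot_fig2(res); dev.off()

print(res)

# how well did the pipeline recover the simulated truth?
truth <- utils::read.delim("results/data/truth.tsv")
print(truth_confusion(truth, res$table))
cat("written: results/{synergy.tsv,fig2.tsv,enrichment.json,fig2.pdf}\n")
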