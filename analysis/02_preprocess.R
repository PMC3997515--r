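#!/usr/bin/env Rscript
# Stage 2: normalization. Quantile-normalize across arrays (removes the
# per-array monotone intensity distortion), then standardize each gene to
# mean 0 / SD 1 so treatment effects are in units of the gene's own SD.
suppressPackageStartupMessages(library(combsig))

m <- read_expression_tsv("results/data/expression.tsv")
norm <- quantile_normalize(m)
z <- per_gene_standardize(norm)

write_expression_tsv(norm, "results/normalized.tsv")
write_expression_tsv(z, "results/standardized.tsv")

excl <- attr(z, "excluded_genes")
cat("quantile-normalized", ncol(norm), "arrays;",
    "column mean spread:", format(max(colMeans(norm)) - min(colMeans(norm))), "\n")
cat("standardized", nrow(z), "genes;", length(excl),
    "zero-variance gene(s) excluded\n")
if (length(excl)) cat("  excluded:", paste(excl, collapse = ", "), "\n")
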